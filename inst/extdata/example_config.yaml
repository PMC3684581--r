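# Desk-scale run configuration (synthetic fixture sizes).
# Paper-scale analyses raise nBackground to 100000 and use real raster
# stacks via loadEnvStack() with the stage functions.
grid:
  source: synthetic
  nRows: 100
  nCols: 100
  nVars: 4
  decoyR: 0.9
scenarios: [mild, strong]
prevalences: [0.1, 0.3, 0.5, 0.7, 0.9]
families: [GAM, GLM, CART, BRT, BIOCLIM, DOMAIN, MAHAL, MAXENT]
nBackground: 5000
rMax: 0.8
alpha: 0.05
aucMin: 0.9
nRepeats: 10
seed: 1
outDir: sdm_run
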
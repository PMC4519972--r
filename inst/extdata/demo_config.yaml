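simulate:
  scaffoldLengths: [300000, 300000, 300000, 300000, 300000,
                    300000, 300000, 300000, 300000, 300000]
  svCounts: {insertion: 30, deletion: 30, duplication: 10, inversion: 8, complex: 2}
  snpRate: 0.001
  readLength: 100
  insertMean: 505
  insertSd: 50
  coverage: 30
  nProgeny: 235
  heterokaryonRate: 0.183
  missingRate: 0.02
  seed: 42
pipeline:
  lodThreshold: 3.0
  maxRf: 0.3
  kbPerCm: 47.7
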
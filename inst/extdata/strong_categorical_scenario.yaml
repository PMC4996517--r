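# Strong-effect three-class interaction scenario: a single causal SNP pair
# (1, 2) with the cyclic odds-ratio pattern (favored class per genotype cell
# cycling as (i + j) mod 3, odds ratio 4), class prevalences 0.3/0.4/0.3,
# 400 samples, 20 SNPs at MAF 0.5.
name: strong-categorical
type: categorical
n: 400
p: 20
maf: 0.5
causal: [1, 2]
prevalence: [0.3, 0.4, 0.3]
odds_ratios:
  - [4, 1, 1]
  - [1, 4, 1]
  - [1, 1, 4]
  - [1, 4, 1]
  - [1, 1, 4]
  - [4, 1, 1]
  - [1, 1, 4]
  - [4, 1, 1]
  - [1, 4, 1]
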
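# Demonstration pipeline configuration: a two-chromosome HS population
# with one SNP-aligned QTL and a full-mediation expression scenario.
seed: 42
simulate:
  n_founders: 8
  n_generations: 70
  n_animals: 200
  family_size: 5
  chromosomes:
    - {name: chr1, length_cM: 60, n_markers: 60}
    - {name: chr2, length_cM: 60, n_markers: 60}
  genotyping_error: 0.01
  missing_rate: 0.01
  qtl:
    - {marker: 30, effects: snp, var_frac: 0.25}
  h2: 0.45
  mediation_scenario: full_mediation
  qtl_frac: 0.25
hmm: {G: 70, eps: 0.01}
scan: {B: 100, alpha: 0.05, r2_min: 0.5}
h2_mcmc: {n_iter: 3000, burn_in: 500}
effects: {M: 15, n_iter: 400, burn_in: 100}
mediation: {fdr: 0.1}
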
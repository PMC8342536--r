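# Shared fixtures and independent oracles.

# Elemental-composition mass oracle: residue formulas Hex C6H10O5,
# HexNAc C8H13NO5, dHex C6H10O4, NeuAc C11H17NO8, summed from atomic
# monoisotopic masses. Independent of the residue-mass constants in R/.
oracle_glycan_mass <- function(H = 0, N = 0, F = 0, S = 0) {
  am <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196)
  atoms <- function(C, Hy, Ni, O) C * am["C"] + Hy * am["H"] + Ni * am["N"] + O * am["O"]
  unname(H * atoms(6, 10, 0, 5) + N * atoms(8, 13, 1, 5) +
         F * atoms(6, 10, 0, 4) + S * atoms(11, 17, 1, 8))
}

random_compositions <- function(n, seed = 42, max_count = 12) {
  set.seed(seed)
  data.frame(H = sample(0:max_count, n, replace = TRUE),
             N = sample(0:max_count, n, replace = TRUE),
             F = sample(0:3, n, replace = TRUE),
             S = sample(0:5, n, replace = TRUE))
}

# Literal Benjamini-Hochberg step-up: for each feature the smallest level
# alpha at which it would be rejected.
brute_force_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- p[p >= p[i] - 1e-15]
    min(vapply(cand, function(t) t * m / sum(p <= t + 1e-15), numeric(1)), 1)
  }, numeric(1))
}

# Long-format glycopeptide records from parallel vectors, with defaults.
make_records <- function(sample_id, glycan, auc, rt = 30,
                         protein = "P1", glycosite = "N100") {
  n <- max(lengths(list(sample_id, glycan, auc, rt, protein, glycosite)))
  data.frame(sample_id = rep_len(sample_id, n),
             protein = rep_len(protein, n),
             glycosite = rep_len(glycosite, n),
             glycan = rep_len(glycan, n),
             rt = rep_len(rt, n), auc = rep_len(auc, n),
             stringsAsFactors = FALSE)
}

# Random protein log-intensity matrix with group labels.
make_protein_matrix <- function(n_prot = 30, n_per_group = 6, sd = 0.5,
                                seed = 7) {
  set.seed(seed)
  groups <- factor(rep(c("Normal", "G1", "G2", "G3"), each = n_per_group),
                   levels = c("Normal", "G1", "G2", "G3"))
  m <- matrix(rnorm(n_prot * length(groups), 25, sd), nrow = n_prot,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              sprintf("S%03d", seq_along(groups))))
  list(mat = m, groups = groups)
}

minimal_run_config <- function(dir, out, seed = 1L, scheme = "pathological") {
  run_config(protein_path = file.path(dir, "proteins.tsv"),
             glyco_path = file.path(dir, "glyco.tsv"),
             metadata_path = file.path(dir, "metadata.tsv"),
             out_dir = out, scheme = scheme, seed = seed,
             min_glycopeptides = 5)
}
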
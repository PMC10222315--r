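# Small in-code fixtures shared across test files.

# a tiny deterministic raw table: 4 samples x 3 metabolites
tiny_table <- function() {
  v <- matrix(c(2, 4, 6,
                1, 2, 9,
                3, 6, 9,
                2, 2, 2),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("case01", "case02", "ctrl01", "ctrl02"),
                              c("met_a", "met_b", "met_c")))
  sample_table(v, c("case", "case", "control", "control"))
}

# random raw table with both groups, log-normal intensities
random_table <- function(n_case = 8, n_control = 10, p = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(rlnorm((n_case + n_control) * p), n_case + n_control, p,
              dimnames = list(sprintf("s%02d", seq_len(n_case + n_control)),
                              paste0("m", seq_len(p))))
  sample_table(v, rep(c("case", "control"), c(n_case, n_control)))
}

# brute-force BH step-up: q(i) = min over j >= i of p(j) * m / j, in input order
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cands <- vapply(rank_i:m, function(j) p[o[j]] * m / j, 0)
    q[i] <- min(1, min(cands))
  }
  q
}

# brute-force AUC over all case/control pairs, ties counting one half
auc_brute <- function(scores, is_case) {
  sc <- scores[is_case]
  sn <- scores[!is_case]
  tot <- 0
  for (a in sc) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sc) * length(sn))
}

ref_path <- function(file) system.file("extdata", file, package = "metevroc")

# the study's published per-metabolite summary statistics (reference inputs)
ref_univariate <- function() read_results(ref_path("st001307_univariate_summary.csv"))
ref_roc <- function() read_results(ref_path("st001307_roc_summary.csv"))

effect_fcs <- c(succinic_acid = 2.04, aminoisobutyric_acid = 0.60,
                butyric_acid = 0.18, isoleucine = 1.63, leucine = 1.73)
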
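# Independent oracles and generators shared across the suite.

# Finite-horizon backward Riccati recursion in the general (B, Q, R) form,
# from terminal cost P_T = Q. Independent of the package's fixed-point
# solver path (which iterates the B = Q = R = I specialisation).
dare_backward <- function(A, horizon = 500L, B = diag(nrow(A)),
                          Q = diag(nrow(A)), R = diag(nrow(A))) {
  P <- Q
  for (t in seq_len(horizon)) {
    BtPB <- t(B) %*% P %*% B
    K <- solve(R + BtPB, t(B) %*% P %*% A)
    P <- Q + t(A) %*% P %*% A - t(A) %*% P %*% B %*% K
    P <- (P + t(P)) / 2
  }
  P
}

# all-pairs Mann-Whitney AUC, ties counted one half
brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# random signed matrix rescaled to a chosen spectral radius
random_stable_matrix <- function(n, rho = 0.9) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m * rho / max(Mod(eigen(m, only.values = TRUE)$values))
}

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

# minimal well-formed interaction table
interactions_df <- function(source, target, mechanism,
                            confidence = NA_real_) {
  data.frame(source = source, target = target, mechanism = mechanism,
             confidence = confidence, stringsAsFactors = FALSE)
}

# the drug-action vocabulary and printed quantification values, frozen
# from the published mechanism table (37 labels)
published_mechanism_values <- c(
  "Activator" = 1, "Adduct" = 0.5, "Agonist" = 1,
  "Allosteric modulator" = 0, "Antagonist" = -1, "Antibody" = 0,
  "Binder" = 0, "Chaperone" = 1, "Chelator" = 0, "Cleavage" = -1,
  "Cofactor" = 1, "Component of" = 0, "Cross-linking/alkylation" = 0,
  "Incorporation into and destabilization" = -1, "Inducer" = 1,
  "Inhibitor" = -1, "Inhibitor, competitive" = -1,
  "Inhibitory allosteric modulator" = -1, "Intercalation" = 0,
  "Ligand" = 0, "Metabolizer" = 0, "Modulator" = 0, "Multitarget" = 0,
  "Negative modulator" = -1, "Neutralizer" = 0, "Other" = 0,
  "Other/unknown" = 0, "Partial agonist" = 1, "Partial antagonist" = -1,
  "Positive allosteric modulator" = 1, "Potentiator" = 1,
  "Product of" = 0, "Reducer" = -1, "Stimulator" = 1, "Suppressor" = -1,
  "Unknown" = 0, "Other terms" = 0)
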
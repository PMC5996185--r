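# Synthetic scenario generator: sparse signed networks, {-1,0,+1} disease
# signatures, and drug panels with planted good/bad/random labels, emitted
# in exactly the table dialects the real readers consume.

# run expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage substream seeds, kept under 2^31
substream <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Generate a random signed directed interaction network
#'
#' Erdos-Renyi-style: each ordered gene pair (no self-loops) becomes an
#' edge independently with probability \code{density}; each edge is
#' labelled \code{inhibition} with probability \code{inhibition_fraction}
#' and \code{activation} otherwise. Gene identifiers are zero-padded
#' (\code{g001}, ...) so the model's sorted gene index preserves numeric
#' order.
#'
#' @param N number of genes (>= 2).
#' @param density edge probability in (0, 1].
#' @param inhibition_fraction probability an edge is inhibitory, in \[0, 1\].
#' @param seed integer seed; same seed, same network.
#' @return data.frame with columns source, target, mechanism, confidence
#'   (all NA: synthetic curated-pathway edges carry no score).
#' @export
generate_network <- function(N, density, inhibition_fraction, seed) {
  stopifnot(N >= 2, density > 0, density <= 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1)
  with_seed(seed, {
    genes <- sprintf("g%0*d", nchar(as.character(N)), seq_len(N))
    pairs <- expand.grid(source = genes, target = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    keep <- stats::runif(nrow(pairs)) < density
    edges <- pairs[keep, , drop = FALSE]
    mech <- ifelse(stats::runif(nrow(edges)) < inhibition_fraction,
                   "inhibition", "activation")
    out <- data.frame(source = edges$source, target = edges$target,
                      mechanism = mech, confidence = NA_real_,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a planted disease signature and its top-table
#'
#' Picks \code{n_dysregulated} model genes uniformly and assigns them +1 or
#' -1 with equal probability; all other genes are 0. The signature is also
#' emitted as a synthetic GEO2R-dialect top-table (columns Gene.symbol,
#' logFC, adj.P.Val) in which planted genes get adj.P.Val < 0.05 and a
#' logFC of matching sign, and unplanted genes get adj.P.Val > 0.05 — so
#' running \code{\link{discretize_expression}} on the table reproduces the
#' planted signature exactly and the reader/discretizer path is exercised
#' end to end.
#'
#' @param model a \code{system_model}.
#' @param n_dysregulated number of nonzero genes, 1 <= n <= N.
#' @param seed integer seed.
#' @return list with \code{signature} (an \code{expression_signature}) and
#'   \code{table} (the GEO2R-dialect data.frame).
#' @export
generate_signature <- function(model, n_dysregulated, seed) {
  stopifnot(inherits(model, "system_model"))
  N <- length(model$genes)
  stopifnot(n_dysregulated >= 1, n_dysregulated <= N)
  with_seed(seed, {
    chosen <- sample(model$genes, n_dysregulated)
    state <- stats::setNames(numeric(N), model$genes)
    state[chosen] <- sample(c(-1, 1), n_dysregulated, replace = TRUE)

    sig_p <- stats::runif(N, 1e-6, 0.049)
    null_p <- stats::runif(N, 0.051, 1)
    magn <- stats::runif(N, 0.5, 3)
    planted <- state != 0
    tab <- data.frame(
      Gene.symbol = model$genes,
      logFC = ifelse(planted, state * magn, (stats::runif(N) - 0.5) * 0.2),
      adj.P.Val = ifelse(planted, sig_p, null_p),
      stringsAsFactors = FALSE)
    signature <- structure(list(values = state, alpha = 0.05,
                                n_skipped = 0L),
                           class = "expression_signature")
    list(signature = signature, table = tab)
  })
}

positive_action_labels <- c("Activator", "Agonist", "Stimulator",
                            "Inducer", "Potentiator")
negative_action_labels <- c("Inhibitor", "Antagonist", "Suppressor",
                            "Reducer", "Negative modulator")

#' Generate a drug panel with planted ground truth
#'
#' "Good" drugs target genes where the optimal intervention is nonzero,
#' with a mechanism whose quantified value matches the intervention sign
#' (so at zero noise their T_d is exactly +1); "bad" drugs use the opposing
#' mechanism (T_d = -1); "random" drugs draw uniform targets and
#' mechanisms. \code{noise} flips each planted good/bad target to the
#' opposing mechanism independently with the given probability.
#'
#' By default the planting is done against the sign of the LQR intervention
#' u(0) computed from the model and signature, which makes the planted
#' truth test the whole scoring chain; \code{plant_against = "signature"}
#' plants against the reversal of the raw disease signature instead (the
#' simpler signature-reversal baseline).
#'
#' Labels map onto the drug-set vocabulary: good -> D1, bad -> D2,
#' random -> D3.
#'
#' @param model a \code{system_model} with dynamics set.
#' @param signature an \code{expression_signature} over model genes.
#' @param n_good,n_bad,n_random panel sizes.
#' @param targets_per_drug targets sampled per drug (default 5).
#' @param noise flip probability in \[0, 1\] (default 0).
#' @param seed integer seed.
#' @param plant_against \code{"hypo"} (default) or \code{"signature"}.
#' @return data.frame with columns drug, set_label, gene, mechanism,
#'   confidence (NA).
#' @export
generate_drug_panel <- function(model, signature, n_good = 10, n_bad = 10,
                                n_random = 0, targets_per_drug = 5,
                                noise = 0, seed = 1,
                                plant_against = c("hypo", "signature")) {
  plant_against <- match.arg(plant_against)
  stopifnot(inherits(model, "system_model"),
            inherits(signature, "expression_signature"),
            noise >= 0, noise <= 1, targets_per_drug >= 1)
  x0 <- align_signature(signature, model)
  target_sign <- if (plant_against == "hypo") {
    sol <- solve_dare(model$dynamics)
    hypo_treatment(sol, model$dynamics, x0)$sign_pattern
  } else {
    -as.numeric(x0)   # ideal intervention reverses the signature
  }
  pool <- model$genes[target_sign != 0]
  if (length(pool) == 0L && (n_good > 0 || n_bad > 0))
    stop("no genes with nonzero intervention sign to plant drugs against")
  names(target_sign) <- model$genes

  with_seed(seed, {
    mech_for <- function(s) {
      if (s > 0) sample(positive_action_labels, 1)
      else sample(negative_action_labels, 1)
    }
    plant <- function(name, label, orient) {
      k <- min(targets_per_drug, length(pool))
      tg <- sample(pool, k)
      mech <- vapply(tg, function(g) {
        s <- orient * target_sign[[g]]
        if (stats::runif(1) < noise) s <- -s
        mech_for(s)
      }, character(1))
      data.frame(drug = name, set_label = label, gene = tg,
                 mechanism = mech, confidence = NA_real_,
                 stringsAsFactors = FALSE)
    }
    random_drug <- function(name) {
      tg <- sample(model$genes, min(targets_per_drug, length(model$genes)))
      mech <- sample(c(positive_action_labels, negative_action_labels),
                     length(tg), replace = TRUE)
      data.frame(drug = name, set_label = "D3", gene = tg,
                 mechanism = mech, confidence = NA_real_,
                 stringsAsFactors = FALSE)
    }
    parts <- c(
      lapply(seq_len(n_good), function(i)
        plant(sprintf("good_%02d", i), "D1", +1)),
      lapply(seq_len(n_bad), function(i)
        plant(sprintf("bad_%02d", i), "D2", -1)),
      lapply(seq_len(n_random), function(i)
        random_drug(sprintf("random_%03d", i))))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic scenario
#'
#' Fans the global seed out into independent per-stage substreams (network,
#' signature, drug panel), so each stage can be regenerated on its own.
#' Defaults describe a sparse disease-pathway-sized system: 100 genes at 5
#' percent edge density with 30 percent inhibitory edges, 20 dysregulated
#' genes, and a panel of 10 therapeutic vs 10 anti-therapeutic drugs.
#'
#' @param N,density,inhibition_fraction network parameters.
#' @param n_dysregulated signature parameter.
#' @param n_good,n_bad,n_random,targets_per_drug,noise,plant_against drug
#'   panel parameters.
#' @param seed global integer seed; same seed and params reproduce the
#'   scenario exactly.
#' @return list with \code{model}, \code{signature},
#'   \code{signature_table}, \code{drugs} (drug-target data.frame),
#'   \code{interactions} (network data.frame), \code{params}, \code{seed}.
#' @export
generate_scenario <- function(N = 100, density = 0.05,
                              inhibition_fraction = 0.3,
                              n_dysregulated = 20, n_good = 10, n_bad = 10,
                              n_random = 0, targets_per_drug = 5, noise = 0,
                              plant_against = "hypo", seed = 1) {
  interactions <- generate_network(N, density, inhibition_fraction,
                                   substream(seed, 1))
  model <- build_model(interactions)
  sig <- generate_signature(model, n_dysregulated, substream(seed, 2))
  drugs <- generate_drug_panel(model, sig$signature, n_good = n_good,
                               n_bad = n_bad, n_random = n_random,
                               targets_per_drug = targets_per_drug,
                               noise = noise, seed = substream(seed, 3),
                               plant_against = plant_against)
  list(model = model, signature = sig$signature,
       signature_table = sig$table, drugs = drugs,
       interactions = interactions,
       params = list(N = N, density = density,
                     inhibition_fraction = inhibition_fraction,
                     n_dysregulated = n_dysregulated, n_good = n_good,
                     n_bad = n_bad, n_random = n_random,
                     targets_per_drug = targets_per_drug, noise = noise,
                     plant_against = plant_against),
       seed = seed)
}

#' Write a synthetic scenario to disk in the consumed table dialects
#'
#' Writes \code{interactions.tsv}, \code{expression.tsv} (GEO2R dialect),
#' and \code{drugs.tsv} under \code{dir}, plus \code{scenario.json} with
#' the generator parameters for provenance.
#'
#' @param scenario output of \code{\link{generate_scenario}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(scenario$interactions, "interactions.tsv")
  wt(scenario$signature_table, "expression.tsv")
  wt(scenario$drugs, "drugs.tsv")
  jsonlite::write_json(c(scenario$params, list(seed = scenario$seed)),
                       file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
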
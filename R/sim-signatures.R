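# Signed gene sets are named integer vectors: names = gene ids, values in
# {+1, -1} (up-/down-regulated in the case arm).

#' Label entity-disease pairs from their signed signatures
#'
#' Classifies every (entity, disease) signature pair by direction agreement on
#' the genes shared between the two signed sets. With `n_opp` shared genes of
#' opposite direction and `n_same` of equal direction, a pair is
#' `anti-correlated` when `n_opp > n_same` and `n_opp >= ceiling(min_share *
#' |disease signature|)`, `correlated` with the roles of `n_opp`/`n_same`
#' swapped, and `null` otherwise. This is the ground-truth analogue of the
#' enrichment-score sign convention: reversal of a substantial share of a
#' disease signature marks a therapeutic (anti-correlated) relationship,
#' mimicry marks a risk (correlated) one.
#'
#' @param entity_signatures named list of signed gene sets.
#' @param disease_signatures named list of signed gene sets.
#' @param min_share minimum agreeing share of the disease signature required
#'   for a non-null label (default 0.25).
#' @return data.frame with columns `entity`, `disease`, `n_same`, `n_opp`,
#'   `label`.
#' @export
signed_agreement_labels <- function(entity_signatures, disease_signatures,
                                    min_share = 0.25) {
  rows <- lapply(names(entity_signatures), function(e) {
    fs <- entity_signatures[[e]]
    do.call(rbind, lapply(names(disease_signatures), function(d) {
      ds <- disease_signatures[[d]]
      shared <- intersect(names(fs), names(ds))
      n_same <- sum(fs[shared] == ds[shared])
      n_opp <- length(shared) - n_same
      thr <- ceiling(min_share * length(ds))
      label <- if (n_opp > n_same && n_opp >= thr) {
        "anti-correlated"
      } else if (n_same > n_opp && n_same >= thr) {
        "correlated"
      } else {
        "null"
      }
      data.frame(
        entity = e, disease = d, n_same = n_same, n_opp = n_opp,
        label = label, stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Flip (or copy) a planted share of a disease signature into a food signature.
reverse_share <- function(disease_sig, fraction, flip = TRUE,
                          which_genes = NULL) {
  m <- length(disease_sig)
  k <- ceiling(fraction * m)
  if (k == 0L) {
    return(setNames(integer(0), character(0)))
  }
  genes <- which_genes %||% sample(names(disease_sig), k)
  sgn <- if (flip) -1L else 1L
  setNames(sgn * disease_sig[genes], genes)
}

add_extra_de <- function(sig, universe, n_extra) {
  if (n_extra <= 0L) {
    return(sig)
  }
  pool <- setdiff(universe, names(sig))
  extra_genes <- sample(pool, min(n_extra, length(pool)))
  extra <- setNames(
    sample(c(-1L, 1L), length(extra_genes), replace = TRUE),
    extra_genes
  )
  c(sig, extra)
}

#' Plant the study's ground truth: signatures, labels, synergy, references
#'
#' Builds all signed signatures and the truth bookkeeping the pipeline is
#' validated against:
#'
#' * each disease signature consists of its interactome module genes plus an
#'   equal number of random off-module genes, each with a random direction;
#' * designated synergistic food pairs split one disease's reversal between
#'   the two foods with partial overlap (each covers
#'   `max(0.6, reversal_fraction)` of the signature, so each partner alone is
#'   anti-correlated, while their union covers it fully);
#' * every remaining food reverses a `reversal_fraction` share of one disease
#'   signature (round-robin over the remaining diseases); every second of
#'   these foods additionally copies (not flips) a share of the next disease's
#'   signature, planting a correlated ("risk") pair;
#' * drugs mirror the non-synergy foods; their planted reversals double as the
#'   known drug indications used for recovery statistics;
#' * every food and drug gains `extra_de_fraction * n_genes` unrelated
#'   differential genes with random directions;
#' * the reference-count table gives each synergy pair's shared disease a
#'   summed count above 10 and every other association a small count, so the
#'   gold-standard builder recovers exactly the planted synergy pairs.
#'
#' `reversal_fraction = 0` disables all reversal planting: no pair is labelled
#' anti-correlated.
#'
#' @param config a [sim_config()].
#' @param modules named list: disease -> module node set (see
#'   [generate_disease_module()]).
#' @return an object of class `planted_truth`: list with
#'   `disease_signatures`, `food_signatures`, `drug_signatures`,
#'   `pair_labels`, `disease_modules`, `synergy_pairs`, `known_indications`,
#'   `reference_table`, `designed_anti`.
#' @export
generate_signatures <- function(config, modules) {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_universe(config)
  diseases <- entity_names("disease", config$n_diseases)
  foods <- entity_names("food", config$n_foods)
  drugs <- entity_names("drug", config$n_drugs)
  if (!setequal(names(modules), diseases)) {
    stop("'modules' must be named by the configured diseases", call. = FALSE)
  }
  rf <- config$reversal_fraction
  set.seed(derive_seed(config$seed, "signatures"))

  # Disease signatures: module genes + same number of off-module genes.
  disease_sigs <- lapply(diseases, function(d) {
    mod <- modules[[d]]
    off <- sample(setdiff(universe, mod), length(mod))
    genes <- c(mod, off)
    setNames(sample(c(-1L, 1L), length(genes), replace = TRUE), genes)
  })
  names(disease_sigs) <- diseases

  n_extra <- ceiling(config$extra_de_fraction * config$n_genes)

  # Synergy planting: pairs (food 2j-1, food 2j) on disease j.
  n_syn <- 0L
  if (config$plant_synergy && rf > 0 && config$n_foods >= 4L) {
    n_syn <- min(config$n_foods %/% 4L, config$n_diseases)
  }
  synergy_pairs <- data.frame(
    food_a = character(0), food_b = character(0), disease = character(0),
    stringsAsFactors = FALSE
  )
  food_sigs <- vector("list", config$n_foods)
  names(food_sigs) <- foods
  designed_anti <- list()

  cov_frac <- max(0.6, rf) # per-partner coverage of the shared reversal
  if (n_syn > 0L) {
    for (j in seq_len(n_syn)) {
      d <- diseases[j]
      ds <- disease_sigs[[d]]
      m <- length(ds)
      k <- ceiling(cov_frac * m)
      ord <- sample(names(ds)) # shuffled split; overlap = 2k - m genes
      fa <- foods[2L * j - 1L]
      fb <- foods[2L * j]
      food_sigs[[fa]] <- reverse_share(ds, cov_frac,
        which_genes = ord[seq_len(k)]
      )
      food_sigs[[fb]] <- reverse_share(ds, cov_frac,
        which_genes = ord[seq.int(m - k + 1L, m)]
      )
      synergy_pairs <- rbind(synergy_pairs, data.frame(
        food_a = fa, food_b = fb, disease = d, stringsAsFactors = FALSE
      ))
      designed_anti[[fa]] <- d
      designed_anti[[fb]] <- d
    }
  }

  # Remaining foods: round-robin reversal over the remaining diseases;
  # every second one also copies a share of the next disease (risk pair).
  remaining_foods <- foods[setdiff(
    seq_len(config$n_foods),
    seq_len(2L * n_syn)
  )]
  remaining_diseases <- diseases[setdiff(
    seq_len(config$n_diseases),
    seq_len(n_syn)
  )]
  if (length(remaining_diseases) == 0L) remaining_diseases <- diseases
  for (i in seq_along(remaining_foods)) {
    f <- remaining_foods[i]
    d <- remaining_diseases[((i - 1L) %% length(remaining_diseases)) + 1L]
    sig <- if (rf > 0) reverse_share(disease_sigs[[d]], rf) else
      setNames(integer(0), character(0))
    if (rf > 0) designed_anti[[f]] <- d
    if (i %% 2L == 0L && rf > 0) {
      d2 <- remaining_diseases[(i %% length(remaining_diseases)) + 1L]
      if (!identical(d2, d)) {
        copied <- reverse_share(disease_sigs[[d2]], rf, flip = FALSE)
        copied <- copied[setdiff(names(copied), names(sig))]
        sig <- c(sig, copied)
      }
    }
    food_sigs[[f]] <- sig
  }
  food_sigs <- lapply(food_sigs, add_extra_de, universe, n_extra)

  # Drugs mirror the simple reversal foods; their planted targets are the
  # known indications.
  drug_sigs <- vector("list", config$n_drugs)
  names(drug_sigs) <- drugs
  known <- data.frame(
    drug = character(0), disease = character(0),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(config$n_drugs)) {
    d <- diseases[((i - 1L) %% config$n_diseases) + 1L]
    sig <- if (rf > 0) reverse_share(disease_sigs[[d]], rf) else
      setNames(integer(0), character(0))
    if (rf > 0) {
      known <- rbind(known, data.frame(
        drug = drugs[i], disease = d,
        stringsAsFactors = FALSE
      ))
    }
    drug_sigs[[drugs[i]]] <- add_extra_de(sig, universe, n_extra)
  }

  labels <- signed_agreement_labels(c(food_sigs, drug_sigs), disease_sigs)
  labels$entity_class <- ifelse(labels$entity %in% foods, "diet", "drug")

  # Reference-count table: planted gold (synergy) pairs get counts summing
  # above 10 on their shared disease; every other association gets a small
  # count, so no other pair can reach the threshold.
  ref <- data.frame(
    food = character(0), disease = character(0),
    reference_count = integer(0), stringsAsFactors = FALSE
  )
  for (j in seq_len(nrow(synergy_pairs))) {
    ref <- rbind(
      ref,
      data.frame(
        food = c(synergy_pairs$food_a[j], synergy_pairs$food_b[j]),
        disease = synergy_pairs$disease[j],
        reference_count = c(6L, 6L), stringsAsFactors = FALSE
      )
    )
  }
  for (f in remaining_foods) {
    d <- designed_anti[[f]]
    if (!is.null(d)) {
      ref <- rbind(ref, data.frame(
        food = f, disease = d, reference_count = 3L,
        stringsAsFactors = FALSE
      ))
    }
  }

  truth <- list(
    # two synthetic disease classes (alternating) for class-level analyses
    disease_classes = setNames(
      ifelse(seq_along(diseases) %% 2L == 1L, "class1", "class2"), diseases
    ),
    disease_signatures = disease_sigs,
    food_signatures = food_sigs,
    drug_signatures = drug_sigs,
    pair_labels = labels,
    disease_modules = modules,
    synergy_pairs = synergy_pairs,
    known_indications = known,
    reference_table = ref,
    designed_anti = designed_anti
  )
  class(truth) <- "planted_truth"
  truth
}

#' @export
print.planted_truth <- function(x, ...) {
  tab <- table(x$pair_labels$label)
  cat("Planted truth:", length(x$disease_signatures), "diseases,",
    length(x$food_signatures), "foods,",
    length(x$drug_signatures), "drugs\n")
  cat("  pair labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  synergy pairs:", nrow(x$synergy_pairs), "\n")
  invisible(x)
}
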
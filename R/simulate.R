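#' Synthetic multi-variant sgRNA activity data
#'
#' Seeded generators for (i) a parental protein compatible with the
#' built-in variant registry and (ii) multi-variant guide-activity tables
#' with planted, recoverable structure: a GC-content effect, a planted
#' positional motif, additive per-variant shifts and bounded Gaussian
#' noise pushed through a logistic link. Every dataset ships with its
#' ground truth so recovery can be checked exactly.
#'
#' @name simulate
NULL

# constant structural scaffold shared by all simulated guides (36 nt)
SCAFFOLD_SEQ <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCT"

#' Generate a synthetic parental protein
#'
#' Residues are uniform over the 20-letter alphabet except at every
#' mutation position of `registry`, which is pinned to that mutation's
#' reference residue so all registry variants apply cleanly.
#'
#' @param length protein length (1368, the Cas9 length, by default).
#' @param registry named list of [variant_definition()]s.
#' @param seed integer seed.
#' @return amino-acid string of the requested length.
#' @export
make_parent <- function(length = CAS9_LENGTH, registry = builtin_registry(),
                        seed = 1L) {
  muts <- unlist(lapply(registry, `[[`, "mutations"), recursive = FALSE)
  pos <- vapply(muts, `[[`, integer(1), "pos")
  ref <- vapply(muts, `[[`, character(1), "ref")
  if (length(pos) && max(pos) > length) {
    stop("parent length ", length, " is shorter than the largest mutation ",
         "position in the registry (", max(pos), ")")
  }
  for (p in unique(pos)) {
    refs <- unique(ref[pos == p])
    if (length(refs) > 1L) {
      stop("registry variants disagree on the reference residue at position ",
           p, ": ", paste(refs, collapse = " vs "))
    }
  }
  set.seed(as.integer(seed))
  res <- sample(AA_ALPHABET, length, replace = TRUE)
  res[pos] <- ref
  paste(res, collapse = "")
}

#' Simulation configuration
#'
#' @param n_guides guides generated per variant.
#' @param variants variant names (must exist in `registry`).
#' @param registry variant registry the names refer to.
#' @param motif planted positional motif: list with `pos` (1-based
#'   protospacer positions), `nt` (favoured nucleotide per position) and
#'   `effect` (additive effect per matched position, recycled).
#' @param gc_effect coefficient on centred protospacer GC fraction.
#' @param variant_effects named additive shifts per variant (default:
#'   evenly spaced on [-1, 1]).
#' @param noise_sd standard deviation of the pre-link Gaussian noise.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_guides = 500L,
                       variants = c("WT-SpCas9", "SpCas9-HF1",
                                    "eSpCas9(1.1)", "SniperCas9"),
                       registry = builtin_registry(),
                       motif = list(pos = c(4L, 9L, 16L),
                                    nt = c("G", "C", "A"),
                                    effect = 1),
                       gc_effect = 4,
                       variant_effects = NULL,
                       noise_sd = 0.3,
                       seed = 1L) {
  stopifnot(n_guides >= 1, noise_sd >= 0, is.finite(gc_effect))
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  missing <- setdiff(variants, names(registry))
  if (length(missing)) {
    stop("variants not in registry: ", paste(missing, collapse = ", "))
  }
  if (is.null(variant_effects)) {
    variant_effects <- stats::setNames(
      if (length(variants) > 1L) seq(-1, 1, length.out = length(variants))
      else 0,
      variants)
  }
  stopifnot(all(variants %in% names(variant_effects)),
            all(is.finite(unlist(variant_effects))))
  motif$effect <- rep_len(motif$effect %||% 1, length(motif$pos))
  stopifnot(all(motif$pos >= 1), all(motif$pos <= PROTOSPACER_LENGTH),
            all(motif$nt %in% c("A", "C", "G", "T")))
  structure(list(n_guides = as.integer(n_guides), variants = variants,
                 registry = registry, motif = motif, gc_effect = gc_effect,
                 variant_effects = variant_effects, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic multi-variant dataset
#'
#' Protospacers are uniform 20-mers, the PAM is NGG with uniform N, and
#' the scaffold is a constant 36-mer. The latent activity of guide i is
#'
#' `logistic(gc_effect * (GC_i - mean GC) + sum of planted-motif effects
#'  (centred indicators) + gamma_variant(i) + eps_i)`, `eps ~ N(0,
#'  noise_sd)`,
#'
#' so activities live in (0, 1) and zero effects give constant 0.5.
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (data.frame: sequence, activity, variant)
#'   and `truth` (noiseless activities, linear predictors, per-guide GC,
#'   motif description, variant effects, config echo).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_total <- cfg$n_guides * length(cfg$variants)
  nts <- c("A", "C", "G", "T")

  proto <- vapply(seq_len(n_total), function(i) {
    paste(sample(nts, PROTOSPACER_LENGTH, replace = TRUE), collapse = "")
  }, character(1))
  pam_n <- sample(nts, n_total, replace = TRUE)
  sequence <- paste0(proto, pam_n, "GG", SCAFFOLD_SEQ)
  variant <- rep(cfg$variants, each = cfg$n_guides)

  gc <- vapply(proto, function(s) {
    mean(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)

  # centred covariates keep the baseline at logistic(0) = 0.5
  eta <- cfg$gc_effect * (gc - 0.5)
  for (m in seq_along(cfg$motif$pos)) {
    hit <- substring(proto, cfg$motif$pos[m], cfg$motif$pos[m]) == cfg$motif$nt[m]
    eta <- eta + cfg$motif$effect[m] * (hit - 0.25)
  }
  eta <- eta + unname(unlist(cfg$variant_effects[variant]))

  eps <- stats::rnorm(n_total, 0, cfg$noise_sd)
  activity <- stats::plogis(eta + eps)
  noiseless <- stats::plogis(eta)

  list(records = data.frame(sequence = sequence, activity = activity,
                            variant = variant, stringsAsFactors = FALSE),
       truth = list(noiseless = noiseless, eta = eta, gc = gc,
                    motif = cfg$motif,
                    variant_effects = cfg$variant_effects,
                    config = cfg))
}

#' Split a generated dataset into per-variant datasets
#'
#' @param sim a [generate_dataset()] result.
#' @return named list of record data.frames, one per variant.
#' @export
split_by_variant <- function(sim) {
  split(sim$records, sim$records$variant)[unique(sim$records$variant)]
}
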
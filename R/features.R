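#' Handcrafted sgRNA descriptor (175 features)
#'
#' A fixed, named 175-feature vector per guide, for downstream
#' feature-importance work: GC content, mono-/di-/tri-nucleotide counts
#' on the 20-nt protospacer, six melting-temperature features, and
#' position-specific nucleotide indicators over the protospacer plus the
#' variable PAM position.
#'
#' @name features
NULL

#' Nearest-neighbour duplex thermodynamic parameters
#'
#' The unified DNA nearest-neighbour parameter set (enthalpies in
#' kcal/mol, entropies in cal/(mol K)) with terminal initiation terms, a
#' symmetry correction for self-complementary duplexes, and defaults of
#' 50 nM strand and 50 mM Na+ (entropy salt correction
#' `0.368 * (N - 1) * ln[Na+]`).
#'
#' @param strand_conc total strand concentration, mol/L.
#' @param na_conc monovalent salt concentration, mol/L.
#' @return a `tm_params` list with `dH`, `dS` (all 16 stacks), initiation
#'   terms and concentrations.
#' @export
nn_tm_params <- function(strand_conc = 5e-8, na_conc = 0.05) {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
          TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
          CC = -19.9)
  structure(list(dH = dH, dS = dS,
                 init_dH_GC = 0.1, init_dS_GC = -2.8,
                 init_dH_AT = 2.3, init_dS_AT = 4.1,
                 sym_dS = -1.4,
                 strand_conc = strand_conc, na_conc = na_conc),
            class = "tm_params")
}

#' @noRd
revcomp_dna <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

#' Nearest-neighbour melting temperature
#'
#' `Tm = dH / (dS + R * ln(C_T / x)) - 273.15` with `dH`, `dS` summed
#' over dinucleotide stacks plus terminal initiation terms, `R` the gas
#' constant in cal/(mol K), `x = 4` for non-self-complementary duplexes
#' (1 for self-complementary, which also gain the symmetry entropy term),
#' and a salt correction on the entropy.
#'
#' @param seq DNA string over {A,C,G,T}, length >= 2.
#' @param params a [nn_tm_params()].
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("GCGCGCGCGC") > melting_temperature("ATATATATAT")
#' @export
melting_temperature <- function(seq, params = nn_tm_params()) {
  stopifnot(inherits(params, "tm_params"))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L) stop("melting temperature needs at least 2 nucleotides")
  if (grepl("[^ACGT]", seq)) {
    stop("melting temperature is defined over {A,C,G,T} only: ", seq)
  }
  stacks <- substring(seq, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  dH <- sum(params$dH[stacks])
  dS <- sum(params$dS[stacks])
  for (end in c(substr(seq, 1L, 1L), substr(seq, n, n))) {
    if (end %in% c("G", "C")) {
      dH <- dH + params$init_dH_GC; dS <- dS + params$init_dS_GC
    } else {
      dH <- dH + params$init_dH_AT; dS <- dS + params$init_dS_AT
    }
  }
  self_comp <- identical(seq, revcomp_dna(seq))
  x <- if (self_comp) 1 else 4
  if (self_comp) dS <- dS + params$sym_dS
  dS <- dS + 0.368 * (n - 1L) * log(params$na_conc)
  R <- 1.987
  dH * 1000 / (dS + R * log(params$strand_conc / x)) - 273.15
}

#' @noRd
kmer_names <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE],
        1L, paste, collapse = "")
}

#' @noRd
count_kmers <- function(seq, k) {
  nm <- kmer_names(k)
  n <- nchar(seq)
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  counts <- stats::setNames(integer(length(nm)), nm)
  tab <- table(kmers)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' The stable feature-name vector (length 175)
#'
#' @return character vector of the 175 feature labels, in extraction
#'   order. Versioned: any change to the list is a breaking change.
#' @export
feature_names <- function() {
  c("GC_content",
    paste0("count_", kmer_names(1)),
    paste0("count_", kmer_names(2)),
    paste0("count_", kmer_names(3)),
    "Tm_protospacer", "Tm_seg_1_5", "Tm_seg_6_13", "Tm_seg_14_20",
    "Tm_proto_pam", "Tm_wallace_gc",
    paste0("Pos_", rep(1:21, each = 4), "_", rep(c("A", "C", "G", "T"), 21)))
}

#' Extract the 175-feature descriptor for one guide
#'
#' Composition features (counts, not frequencies, unless
#' `frequencies = TRUE`) are computed on the 20-nt protospacer; the six Tm
#' features cover the full protospacer, its 1-5 / 6-13 / 14-20 segments,
#' the 23-nt protospacer+PAM region and a GC-corrected Wallace-style
#' estimate; positional indicators are 1-based from the protospacer 5'
#' end and include the variable PAM 'N' position (position 21).
#'
#' @param sequence one 59-nt guide sequence.
#' @param params Tm parameter set.
#' @param frequencies divide k-mer counts by the number of k-mer windows.
#' @param on_n how to treat 'N' inside the protospacer: `"error"`
#'   (default) or `"zero"` (zero-fill composition/Tm features with a
#'   warning).
#' @return named numeric vector of length 175.
#' @export
extract_features <- function(sequence, params = nn_tm_params(),
                             frequencies = FALSE,
                             on_n = c("error", "zero")) {
  on_n <- match.arg(on_n)
  sequence <- normalize_sgrna(sequence)
  stopifnot(length(sequence) == 1L)
  proto <- substr(sequence, 1L, PROTOSPACER_LENGTH)
  proto_pam <- substr(sequence, 1L, PROTOSPACER_LENGTH + PAM_LENGTH)
  nms <- feature_names()
  out <- stats::setNames(numeric(length(nms)), nms)

  has_n <- grepl("N", proto, fixed = TRUE)
  if (has_n && on_n == "error") {
    stop("protospacer contains 'N'; composition and Tm features are ",
         "undefined (set on_n = \"zero\" to zero-fill)")
  }
  if (!has_n) {
    c1 <- count_kmers(proto, 1L)
    c2 <- count_kmers(proto, 2L)
    c3 <- count_kmers(proto, 3L)
    if (frequencies) {
      c1 <- c1 / 20; c2 <- c2 / 19; c3 <- c3 / 18
    }
    out["GC_content"] <- (sum(count_kmers(proto, 1L)[c("C", "G")])) / 20
    out[paste0("count_", names(c1))] <- c1
    out[paste0("count_", names(c2))] <- c2
    out[paste0("count_", names(c3))] <- c3
    out["Tm_protospacer"] <- melting_temperature(proto, params)
    out["Tm_seg_1_5"] <- melting_temperature(substr(proto, 1, 5), params)
    out["Tm_seg_6_13"] <- melting_temperature(substr(proto, 6, 13), params)
    out["Tm_seg_14_20"] <- melting_temperature(substr(proto, 14, 20), params)
    out["Tm_proto_pam"] <- if (grepl("N", proto_pam, fixed = TRUE)) {
      # variable PAM position unknown: fall back to the protospacer value
      out["Tm_protospacer"]
    } else {
      melting_temperature(proto_pam, params)
    }
    gc_n <- sum(count_kmers(proto, 1L)[c("C", "G")])
    out["Tm_wallace_gc"] <- 64.9 + 41 * (gc_n - 16.4) / 20
  } else {
    warning("protospacer contains 'N'; composition and Tm features zero-filled")
  }

  chars <- strsplit(substr(sequence, 1L, 21L), "", fixed = TRUE)[[1]]
  for (i in seq_len(21L)) {
    if (chars[i] %in% c("A", "C", "G", "T")) {
      out[paste0("Pos_", i, "_", chars[i])] <- 1
    }
  }
  out
}

#' Feature matrix for a record table
#'
#' @param records sgRNA record data.frame.
#' @param ... forwarded to [extract_features()].
#' @return `n x 175` numeric matrix with feature-name columns.
#' @export
extract_feature_matrix <- function(records, ...) {
  out <- t(vapply(records$sequence, extract_features, numeric(175L), ...,
                  USE.NAMES = FALSE))
  colnames(out) <- feature_names()
  out
}
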
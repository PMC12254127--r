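#' sgRNA record layout
#'
#' Guides are handled as 59-nt sequences: a 20-nt protospacer, a 3-nt PAM
#' (NGG for SpCas9) and a 36-nt constant scaffold. Records travel as a
#' data.frame with columns `sequence`, `activity` and `variant`.
#'
#' @name sgrna-records
NULL

SGRNA_LENGTH <- 59L
PROTOSPACER_LENGTH <- 20L
PAM_LENGTH <- 3L
SCAFFOLD_LENGTH <- 36L
NT_CHANNELS <- c("A", "C", "G", "T", "N")

#' Normalise and validate guide sequences
#'
#' Upper-cases, maps RNA 'U' to 'T' and checks length and alphabet.
#'
#' @param sequence character vector of guide sequences.
#' @param strict if `TRUE` (default) sequences of the wrong length are an
#'   error; otherwise they are right-padded with 'N' / truncated to 59 nt
#'   with a warning (for foreign table dialects).
#' @return normalised character vector.
#' @export
normalize_sgrna <- function(sequence, strict = TRUE) {
  seq <- chartr("u", "U", toupper(sequence))
  seq <- chartr("U", "T", seq)
  len <- nchar(seq)
  if (any(len != SGRNA_LENGTH)) {
    if (strict) {
      bad <- which(len != SGRNA_LENGTH)[1L]
      stop("sgRNA sequence ", bad, " has length ", len[bad],
           "; expected ", SGRNA_LENGTH, " nt (20-nt protospacer + 3-nt PAM + 36-nt scaffold)")
    }
    warning("padding/truncating ", sum(len != SGRNA_LENGTH),
            " sequence(s) to ", SGRNA_LENGTH, " nt")
    seq <- vapply(seq, function(s) {
      if (nchar(s) > SGRNA_LENGTH) {
        substr(s, 1L, SGRNA_LENGTH)
      } else {
        paste0(s, strrep("N", SGRNA_LENGTH - nchar(s)))
      }
    }, character(1), USE.NAMES = FALSE)
  }
  bad <- grepl(paste0("[^", paste(NT_CHANNELS, collapse = ""), "]"), seq)
  if (any(bad)) {
    stop("sgRNA sequence contains symbols outside {A,C,G,T,N}: ",
         seq[which(bad)[1L]])
  }
  seq
}

#' Read an sgRNA activity table
#'
#' Reads a delimited text file with columns `sequence`, `activity` and
#' `variant` (extra columns are kept), normalises the sequences and checks
#' activities are finite.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the extension;
#'   `.tsv`/`.txt` are tab, anything else comma).
#' @param strict see [normalize_sgrna()].
#' @return data.frame of validated records.
#' @export
read_sgrna_table <- function(path, strict = TRUE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sequence", "activity", "variant")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sgRNA table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$sequence <- normalize_sgrna(df$sequence, strict = strict)
  df$activity <- as.numeric(df$activity)
  if (any(!is.finite(df$activity))) {
    stop("sgRNA table contains non-finite activity values")
  }
  df$variant <- as.character(df$variant)
  df
}

#' Write an sgRNA activity table
#'
#' @param records data.frame with `sequence`, `activity`, `variant`.
#' @param path output CSV path.
#' @export
write_sgrna_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}

#' One-hot encode guide sequences
#'
#' Encodes each 59-nt guide over the five channels (A, C, G, T, N), one
#' indicator per position.
#'
#' @param sequence a single sequence or character vector (normalised with
#'   [normalize_sgrna()] first).
#' @return for one sequence, a 59 x 5 binary matrix with channel column
#'   names; for several, a stacked `(n * 59) x 5` matrix with attributes
#'   `n_samples` and `L` (the layout the encoder consumes).
#' @export
one_hot_encode <- function(sequence) {
  sequence <- normalize_sgrna(sequence)
  n <- length(sequence)
  chars <- strsplit(paste(sequence, collapse = ""), "", fixed = TRUE)[[1]]
  code <- match(chars, NT_CHANNELS)
  X <- matrix(0, n * SGRNA_LENGTH, length(NT_CHANNELS),
              dimnames = list(NULL, NT_CHANNELS))
  X[cbind(seq_along(code), code)] <- 1
  attr(X, "n_samples") <- n
  attr(X, "L") <- SGRNA_LENGTH
  X
}
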
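#' Cas9 variant construction from point-mutation specifications
#'
#' Engineered Cas9 variants (SpCas9-HF1, eSpCas9(1.1), HypaCas9, SniperCas9,
#' evoCas9, xCas9) differ from wild-type S. pyogenes Cas9 by a handful of
#' amino-acid substitutions. This module parses substitution tokens in the
#' standard protein-mutation notation (e.g. "R661A": Arg at residue 661
#' replaced by Ala, 1-based), applies them to a parental sequence, and
#' recovers them by per-position diffing.
#'
#' @name variants
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CAS9_LENGTH <- 1368L

#' Parse a point-mutation token
#'
#' @param token string of the form `<ref><position><alt>`, e.g. "R661A"
#'   (case-insensitive on the letters).
#' @return a `mutation_spec`: list with `ref`, `pos` (1-based integer),
#'   `alt`.
#' @examples
#' parse_mutation("R661A")
#' @export
parse_mutation <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  tok <- toupper(trimws(token))
  m <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z])$", tok))[[1]]
  if (length(m) != 4L) {
    stop("malformed mutation token: '", token,
         "' (expected <ref><position><alt>, e.g. R661A)")
  }
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  if (!(ref %in% AA_ALPHABET)) {
    stop("unknown amino-acid letter '", ref, "' in token '", token, "'")
  }
  if (!(alt %in% AA_ALPHABET)) {
    stop("unknown amino-acid letter '", alt, "' in token '", token, "'")
  }
  if (pos < 1L) stop("mutation position must be >= 1 in token '", token, "'")
  if (ref == alt) {
    stop("degenerate substitution in token '", token,
         "': reference and alternate residue are identical")
  }
  structure(list(ref = ref, pos = pos, alt = alt),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) paste0(x$ref, x$pos, x$alt)

#' @export
print.mutation_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Define a named Cas9 variant
#'
#' @param name variant label, e.g. "xCas9".
#' @param mutations character vector of mutation tokens (possibly empty,
#'   for the wild type).
#' @return a `variant_definition`: list with `name` and a list of parsed
#'   `mutation_spec`s. Duplicate positions are rejected.
#' @export
variant_definition <- function(name, mutations = character()) {
  specs <- lapply(mutations, parse_mutation)
  pos <- vapply(specs, `[[`, integer(1), "pos")
  if (anyDuplicated(pos)) {
    stop("variant '", name, "' lists duplicate mutation positions: ",
         paste(pos[duplicated(pos)], collapse = ", "))
  }
  structure(list(name = name, mutations = specs),
            class = "variant_definition")
}

#' @export
print.variant_definition <- function(x, ...) {
  toks <- vapply(x$mutations, format, character(1))
  cat("Cas9 variant '", x$name, "': ",
      if (length(toks)) paste(toks, collapse = ", ") else "no mutations (wild type)",
      "\n", sep = "")
  invisible(x)
}

#' Built-in Cas9 variant registry
#'
#' The seven SpCas9 variants handled by the model, as ordered lists of
#' point substitutions on the 1368-residue parental protein.
#'
#' @return named list of [variant_definition()] objects.
#' @examples
#' names(builtin_registry())
#' builtin_registry()[["xCas9"]]
#' @export
builtin_registry <- function() {
  defs <- list(
    "WT-SpCas9"    = character(),
    "SpCas9-HF1"   = c("N497A", "R661A", "Q695A", "Q926A"),
    "eSpCas9(1.1)" = c("K848A", "K1003A", "R1060A"),
    "HypaCas9"     = c("N692A", "M694A", "Q695A", "H698A"),
    "SniperCas9"   = c("F539S", "M763I", "K890N"),
    "evoCas9"      = c("M495V", "Y515N", "K526E", "R661Q"),
    "xCas9"        = c("A262T", "R324L", "S409I", "E480K", "E543D", "M694I", "E1219V")
  )
  mapply(variant_definition, names(defs), defs, SIMPLIFY = FALSE)
}

#' Apply a variant's mutations to a parental protein
#'
#' Every mutation's reference residue is checked against the parent; a
#' mismatch signals the wrong parental template and is a hard error.
#'
#' @param parent parental amino-acid sequence (single string).
#' @param defn a [variant_definition()].
#' @return the mutated sequence, same length as `parent`.
#' @export
apply_mutations <- function(parent, defn) {
  stopifnot(inherits(defn, "variant_definition"))
  parent <- validate_protein(parent)
  res <- strsplit(parent, "", fixed = TRUE)[[1]]
  for (mut in defn$mutations) {
    if (mut$pos > length(res)) {
      stop("mutation ", format(mut), " is out of range for a parent of length ",
           length(res))
    }
    if (res[mut$pos] != mut$ref) {
      stop("reference-residue mismatch for ", format(mut), ": parent has '",
           res[mut$pos], "' at position ", mut$pos,
           " (wrong parental template?)")
    }
    res[mut$pos] <- mut$alt
  }
  paste(res, collapse = "")
}

#' Diff two equal-length protein sequences
#'
#' @param a,b amino-acid strings of equal length.
#' @return list of `mutation_spec`s transforming `a` into `b`, ordered by
#'   position (empty when identical). Verification counterpart of
#'   [apply_mutations()].
#' @export
diff_sequences <- function(a, b) {
  a <- validate_protein(a); b <- validate_protein(b)
  if (nchar(a) != nchar(b)) {
    stop("cannot diff sequences of different lengths (", nchar(a),
         " vs ", nchar(b), ")")
  }
  ra <- strsplit(a, "", fixed = TRUE)[[1]]
  rb <- strsplit(b, "", fixed = TRUE)[[1]]
  pos <- which(ra != rb)
  lapply(pos, function(p) {
    structure(list(ref = ra[p], pos = p, alt = rb[p]), class = "mutation_spec")
  })
}

#' @noRd
validate_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty protein sequence")
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seq)) {
    stop("protein sequence contains symbols outside the 20-letter amino-acid alphabet")
  }
  seq
}

#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings for the parental and variant sequences.
#'
#' @param path FASTA file path.
#' @return `read_protein_fasta`: named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname read_protein_fasta
#' @param sequences named character vector of amino-acid sequences.
#' @export
write_protein_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Load variant definitions from a YAML/JSON file
#'
#' The file maps variant names to lists of mutation tokens, mirroring the
#' built-in registry, e.g. `{"MyCas9": ["R661A", "Q695A"]}`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list of [variant_definition()]s.
#' @export
read_variant_definitions <- function(path) {
  defs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- lapply(names(defs), function(nm) {
    toks <- defs[[nm]]
    if (is.null(toks) || identical(toks, "") || !length(toks)) toks <- character()
    variant_definition(nm, as.character(toks))
  })
  stats::setNames(out, names(defs))
}
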
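#' Protein embedding backends
#'
#' The model consumes an `L x D` per-residue embedding of the Cas9 variant
#' protein and is agnostic about where it comes from. Two backends are
#' declared:
#'
#' * `"stub"` (default): a deterministic embedder that maps each residue
#'   -- optionally keyed by a window of `context_k` neighbours on each
#'   side -- to a fixed pseudo-random `width`-vector drawn from a seeded
#'   generator. It is bit-reproducible across machines, requires no
#'   external runtime, and is the backend all tests and simulations use.
#' * `"esm2"`: the 650M-parameter ESM2 protein language model, whose
#'   per-residue width (1280) the default stub mirrors. It needs a Python
#'   checkpoint runtime that is not bundled; selecting it without one
#'   raises an error pointing at the stub.
#'
#' @param name backend name, `"stub"` or `"esm2"`.
#' @param width per-residue embedding width D (default 1280).
#' @param context_k number of flanking residues hashed into each
#'   position's key (0 = residue identity only, the default).
#' @param seed integer seed fixing the stub's vector table.
#' @return an `embedder_backend` object.
#' @export
embedder_backend <- function(name = c("stub", "esm2"), width = 1280L,
                             context_k = 0L, seed = 1L) {
  name <- match.arg(name)
  structure(list(name = name, width = as.integer(width),
                 context_k = as.integer(context_k), seed = as.integer(seed)),
            class = "embedder_backend")
}

#' @export
print.embedder_backend <- function(x, ...) {
  cat("Protein embedder backend '", x$name, "' (width ", x$width,
      ", context_k ", x$context_k, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# in-memory embedding cache shared across calls
.embed_cache <- new.env(parent = emptyenv())

#' @noRd
#' Stable 31-bit string hash (order-sensitive polynomial in a Mersenne
#' prime field) used for cache keys and stub vector seeds.
string_hash <- function(s, seed = 0L) {
  codes <- utf8ToInt(s)
  h <- as.numeric(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' @noRd
#' Draw the stub vector for one context key without disturbing the
#' caller's RNG stream.
stub_vector <- function(key, width, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(string_hash(key, seed))
  stats::rnorm(width)
}

#' Embed a protein sequence
#'
#' Returns the `L x D` per-residue embedding for `seq` under `backend`.
#' Results are cached in memory (and, when `cache_dir` is given, on disk
#' as RDS files keyed by backend name and sequence digest with a JSON
#' manifest), so each variant is embedded once per session: variants are
#' few while guides are many.
#'
#' @param seq amino-acid sequence (single string).
#' @param backend an [embedder_backend()].
#' @param cache_dir optional directory for a persistent cache.
#' @return numeric `L x D` matrix, one row per residue.
#' @export
embed_protein <- function(seq, backend = embedder_backend(), cache_dir = NULL) {
  stopifnot(inherits(backend, "embedder_backend"))
  seq <- validate_protein(seq)
  if (backend$name == "esm2") {
    stop("the ESM2 backend requires an external protein-language-model ",
         "runtime that is not installed; use embedder_backend(\"stub\") ",
         "for a deterministic offline embedder of the same width")
  }
  key <- paste0(backend$name, ":", backend$width, ":", backend$context_k,
                ":", backend$seed, ":", string_hash(seq), ":", nchar(seq))
  hit <- .embed_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!is.null(cache_dir)) {
    file <- file.path(cache_dir, paste0(gsub("[^A-Za-z0-9]", "_", key), ".rds"))
    if (file.exists(file)) {
      emb <- readRDS(file)
      .embed_cache[[key]] <- emb
      return(emb)
    }
  }

  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(res)
  k <- backend$context_k
  padded <- c(rep("-", k), res, rep("-", k))
  ctx <- vapply(seq_len(L), function(i) {
    paste(padded[i:(i + 2L * k)], collapse = "")
  }, character(1))
  uniq <- unique(ctx)
  table <- matrix(0, length(uniq), backend$width)
  for (i in seq_along(uniq)) {
    table[i, ] <- stub_vector(uniq[i], backend$width, backend$seed)
  }
  emb <- table[match(ctx, uniq), , drop = FALSE]

  .embed_cache[[key]] <- emb
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(emb, file)
    manifest <- file.path(cache_dir, "manifest.json")
    entries <- if (file.exists(manifest)) {
      jsonlite::read_json(manifest, simplifyVector = FALSE)
    } else {
      list()
    }
    entries[[key]] <- list(backend = backend$name, width = backend$width,
                           context_k = backend$context_k, seed = backend$seed,
                           length = L, file = basename(file))
    jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  emb
}

#' Embed every variant in a registry
#'
#' Convenience wrapper: applies each variant definition to the parent and
#' embeds the resulting protein.
#'
#' @param parent parental protein sequence.
#' @param registry named list of [variant_definition()]s (default: the
#'   built-in seven-variant registry).
#' @param backend an [embedder_backend()].
#' @param cache_dir optional persistent cache directory.
#' @return named list of `L x D` embedding matrices.
#' @export
embed_variants <- function(parent, registry = builtin_registry(),
                           backend = embedder_backend(), cache_dir = NULL) {
  lapply(registry, function(defn) {
    embed_protein(apply_mutations(parent, defn), backend, cache_dir)
  })
}
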
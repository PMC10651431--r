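#' Backbone specifications
#'
#' A backbone turns an amino-acid sequence of length N into an
#' (N+2) x D matrix of per-token representations: row 1 is the CLS
#' (whole-sequence) token, rows 2..N+1 the residues, row N+2 the END
#' token. `backbone_mock()` is a deterministic stand-in for a protein
#' language model, suitable for CPU-only training and testing:
#' each residue row is a pure function of (residue identity, position,
#' seed) — and of the residues inside the `locality` window, when that is
#' positive — while the CLS row depends on the whole sequence. A real
#' protein language model (e.g. a 1280-wide transformer run
#' out-of-process) plugs in through `backbone_custom()` by supplying a
#' function `sequence -> (N+2) x D matrix`.
#'
#' @param width Embedding width D.
#' @param seed Seed fixing the mock's state.
#' @param locality Half-width of the residue window a row may depend on
#'   (default 0: a single-residue change alters exactly that residue row
#'   plus the CLS row).
#' @param max_len Maximum sequence length accepted.
#' @return A `protstab_backbone` object.
#' @export
backbone_mock <- function(width = 16L, seed = 1L, locality = 0L,
                          max_len = 1022L) {
  abort_if(width < 1, "width must be >= 1")
  structure(list(kind = "mock", name = sprintf("mock-%d", width),
                 width = as.integer(width), seed = as.integer(seed),
                 locality = as.integer(locality),
                 max_len = as.integer(max_len), trainable = FALSE),
            class = "protstab_backbone")
}

#' @rdname backbone_mock
#' @param fn Function mapping a sequence string to an (N+2) x D matrix.
#' @param name Label for the adapter.
#' @param trainable Whether the backbone exposes trainable state.
#' @export
backbone_custom <- function(fn, width, name = "custom",
                            max_len = 1022L, trainable = FALSE) {
  abort_if(!is.function(fn), "fn must be a function(sequence) -> matrix")
  abort_if(width < 1, "width must be >= 1")
  structure(list(kind = "custom", name = name, width = as.integer(width),
                 fn = fn, max_len = as.integer(max_len),
                 trainable = trainable),
            class = "protstab_backbone")
}

#' @export
print.protstab_backbone <- function(x, ...) {
  cat(sprintf("protstab_backbone '%s' (kind %s, width %d, max_len %d)\n",
              x$name, x$kind, x$width, x$max_len))
  invisible(x)
}

#' Resolve a backbone from a configuration list
#'
#' Config-key selection used by file-driven workflows:
#' `list(kind = "mock", width = ..., seed = ...)`.
#'
#' @param config Named list with at least `kind`.
#' @return A `protstab_backbone`.
#' @export
backbone_from_config <- function(config) {
  kind <- config$kind %||% "mock"
  switch(kind,
         mock = backbone_mock(width = config$width %||% 16L,
                              seed = config$seed %||% 1L,
                              locality = config$locality %||% 0L,
                              max_len = config$max_len %||% 1022L),
         stop(sprintf("unknown backbone kind '%s' (use 'mock', or build a %s",
                      kind, "backbone_custom() adapter in code)"),
              call. = FALSE))
}

check_sequence <- function(sequence, backbone) {
  abort_if(!is.character(sequence) || length(sequence) != 1,
           "sequence must be a single string")
  abort_if(nchar(sequence) == 0, "empty sequence: no residues to embed")
  abort_if(nchar(sequence) > backbone$max_len,
           "sequence length %d exceeds backbone maximum %d",
           nchar(sequence), backbone$max_len)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  abort_if(length(bad) > 0,
           "illegal character '%s' at position %d",
           chars[bad[1]], bad[1])
  chars
}

#' Deterministic mock per-token embedding
#'
#' Expands a seeded hash of (residue identity, position, seed) — plus the
#' residues inside the locality window — into each residue row; the CLS
#' row hashes the whole sequence and the END row the sequence length.
#' Distinct sequences therefore receive distinct matrices, and a
#' single-residue change alters exactly the rows within the locality
#' window plus the CLS row. Bitwise reproducible; never touches the
#' caller's RNG state.
#'
#' @param sequence Amino-acid string.
#' @param width Embedding width D.
#' @param seed Integer seed.
#' @param locality Window half-width (see [backbone_mock()]).
#' @return An (N+2) x width numeric matrix.
#' @export
mock_embed <- function(sequence, width, seed = 1L, locality = 0L) {
  chars <- check_sequence(sequence, list(max_len = .Machine$integer.max))
  n <- length(chars)
  keys <- character(n + 2)
  keys[1] <- paste("CLS", sequence)
  for (i in seq_len(n)) {
    lo <- max(1L, i - locality)
    hi <- min(n, i + locality)
    keys[i + 1] <- paste("RES", i, paste(chars[lo:hi], collapse = ""))
  }
  keys[n + 2] <- paste("END", n)
  with_seed(seed, {
    rows <- lapply(keys, function(k) {
      set.seed(hash31(seed, k))
      rnorm(width)
    })
    do.call(rbind, rows)
  })
}

#' Embed a sequence with a backbone
#'
#' Validates the sequence (alphabet, non-empty, within the backbone's
#' context length) and returns the (N+2) x D per-token matrix. For a
#' fixed backbone state the output is a deterministic function of the
#' sequence.
#'
#' @param sequence Amino-acid string.
#' @param backbone A `protstab_backbone`.
#' @return An (N+2) x D numeric matrix.
#' @export
embed_sequence <- function(sequence, backbone) {
  check_sequence(sequence, backbone)
  emb <- switch(backbone$kind,
                mock = mock_embed(sequence, backbone$width, backbone$seed,
                                  backbone$locality),
                custom = backbone$fn(sequence),
                stop("unknown backbone kind", call. = FALSE))
  abort_if(!is.matrix(emb) ||
             nrow(emb) != nchar(sequence) + 2 ||
             ncol(emb) != backbone$width,
           "backbone returned shape (%d, %d); expected (%d, %d)",
           nrow(emb), ncol(emb), nchar(sequence) + 2, backbone$width)
  abort_if(any(!is.finite(emb)), "backbone returned non-finite values")
  emb
}

#' Extract the token row at a mutation position
#'
#' Positions are 1-based indices into the sequence; the +1 shift for the
#' CLS row is internal to this accessor, the single place the offset
#' convention lives.
#'
#' @param embedding An (N+2) x D matrix from [embed_sequence()].
#' @param position 1-based residue position, in 1..N.
#' @return Numeric vector of width D.
#' @export
mutation_row <- function(embedding, position) {
  n <- nrow(embedding) - 2L
  abort_if(position < 1L || position > n,
           "position %d out of range 1..%d", position, n)
  embedding[position + 1L, ]
}

#' CLS (whole-sequence) row of an embedding
#'
#' @param embedding An (N+2) x D matrix.
#' @return Numeric vector of width D.
#' @export
cls_row <- function(embedding) embedding[1L, ]

# per-session embedding cache keyed by (backbone name, seed, sequence);
# mock embeddings are pure functions, so caching is safe
embedding_cache <- function() new.env(parent = emptyenv())

embed_cached <- function(sequence, backbone, cache = NULL) {
  if (is.null(cache)) return(embed_sequence(sequence, backbone))
  key <- paste(backbone$name, backbone$seed %||% 0, sequence)
  if (is.null(cache[[key]])) cache[[key]] <- embed_sequence(sequence, backbone)
  cache[[key]]
}
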
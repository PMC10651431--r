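#' Specify an embedding-combination regression head
#'
#' A head combines the wild-type and mutant token embeddings into one
#' feature vector and maps it to a scalar ddG through a network with one
#' hidden layer. Exactly five (source, merge) combinations are
#' admissible:
#' \itemize{
#'   \item `position` + `concatenation` — the two mutation-position rows
#'     side by side (width 2D);
#'   \item `position` + `outer_product` — flattened D x D outer product
#'     of the two mutation-position rows;
#'   \item `position` + `linear` — element-wise weighted sum
#'     `w_wt * e_wt + w_mt * e_mt` (width D);
#'   \item `cls` + `linear` — the same weighted sum on the CLS rows;
#'   \item `cls_position` + `linear` — the weighted sum on the
#'     concatenation of CLS and mutation-position rows (width 2D).
#' }
#'
#' @param source One of `"position"`, `"cls"`, `"cls_position"`.
#' @param merge One of `"concatenation"`, `"outer_product"`, `"linear"`.
#' @param hidden Width of the hidden layer (default 32; the reference
#'   architecture does not fix it).
#' @param antisymmetric If `TRUE` (linear merges only), ties
#'   `w_mt = -w_wt` and pins all biases at zero so that
#'   `predict(a, b) == -predict(b, a)` holds structurally. Off by
#'   default: symmetry is normally learned from reverse-augmented data.
#' @param outer_cap Maximum embedding width for which the D^2 outer
#'   product is materialized; wider backbones raise an error instructing
#'   use of a narrower one.
#' @return A `head_spec` object.
#' @export
head_spec <- function(source = c("position", "cls", "cls_position"),
                      merge = c("concatenation", "outer_product", "linear"),
                      hidden = 32L, antisymmetric = FALSE,
                      outer_cap = 4096L) {
  source <- match.arg(source)
  merge <- match.arg(merge)
  allowed <- list(c("position", "concatenation"),
                  c("position", "outer_product"),
                  c("position", "linear"),
                  c("cls", "linear"),
                  c("cls_position", "linear"))
  ok <- any(vapply(allowed, function(a)
    identical(a, c(source, merge)), TRUE))
  abort_if(!ok, "inadmissible head: source '%s' with merge '%s'",
           source, merge)
  abort_if(antisymmetric && merge != "linear",
           "antisymmetric tying is defined for linear merges only")
  structure(list(source = source, merge = merge,
                 hidden = as.integer(hidden),
                 antisymmetric = antisymmetric,
                 outer_cap = as.integer(outer_cap)),
            class = "head_spec")
}

#' The five admissible head specifications
#'
#' @param hidden Hidden width applied to all five.
#' @param antisymmetric Antisymmetric tying for the linear-merge heads.
#' @return Named list of five [head_spec()] objects.
#' @export
five_head_specs <- function(hidden = 32L, antisymmetric = FALSE) {
  list(
    position_concat = head_spec("position", "concatenation", hidden),
    position_outer = head_spec("position", "outer_product", hidden),
    position_linear = head_spec("position", "linear", hidden,
                                antisymmetric),
    cls_linear = head_spec("cls", "linear", hidden, antisymmetric),
    cls_position_linear = head_spec("cls_position", "linear", hidden,
                                    antisymmetric)
  )
}

#' Width of the combined feature vector
#'
#' Concatenation gives 2D, the outer product D^2, the linear merge D (or
#' 2D when the source is `cls_position`).
#'
#' @param spec A [head_spec()].
#' @param width Embedding width D.
#' @return Integer feature width.
#' @export
feature_width <- function(spec, width) {
  switch(spec$merge,
         concatenation = 2L * width,
         outer_product = width^2,
         linear = if (spec$source == "cls_position") 2L * width
         else as.integer(width))
}

# rows of the embedding the head's source selects
select_source <- function(spec, embedding, position) {
  switch(spec$source,
         position = mutation_row(embedding, position),
         cls = cls_row(embedding),
         cls_position = c(cls_row(embedding),
                          mutation_row(embedding, position)))
}

#' Combine wild-type and mutant embeddings into head features
#'
#' Selects the rows named by the head's source and merges them. The
#' linear merge multiplies each selected vector element-wise with its
#' weight vector and sums; identity/zero weights therefore reproduce the
#' selected rows exactly.
#'
#' @param spec A [head_spec()] (or a trained head, whose weights are
#'   then used).
#' @param wt_embedding,mt_embedding (N+2) x D matrices.
#' @param position 1-based mutation position.
#' @param w_wt,w_mt Weight vectors for the linear merge (default all
#'   ones).
#' @return Numeric feature vector of [feature_width()].
#' @export
combine_embeddings <- function(spec, wt_embedding, mt_embedding, position,
                               w_wt = NULL, w_mt = NULL) {
  if (inherits(spec, "protstab_head")) {
    w_wt <- w_wt %||% spec$params$w_wt
    w_mt <- w_mt %||% spec$params$w_mt
    spec <- spec$spec
  }
  abort_if(ncol(wt_embedding) != ncol(mt_embedding),
           "embedding width mismatch: %d vs %d",
           ncol(wt_embedding), ncol(mt_embedding))
  e_wt <- select_source(spec, wt_embedding, position)
  e_mt <- select_source(spec, mt_embedding, position)
  switch(spec$merge,
         concatenation = c(e_wt, e_mt),
         outer_product = {
           abort_if(ncol(wt_embedding) > spec$outer_cap,
                    "outer product at width %d exceeds cap %d; %s",
                    ncol(wt_embedding), spec$outer_cap,
                    "use a narrower backbone")
           as.vector(outer(e_wt, e_mt))
         },
         linear = {
           w_wt <- w_wt %||% rep(1, length(e_wt))
           w_mt <- w_mt %||% rep(1, length(e_mt))
           abort_if(length(w_wt) != length(e_wt) ||
                      length(w_mt) != length(e_mt),
                    "weight vector width mismatch")
           w_wt * e_wt + w_mt * e_mt
         })
}

#' Initialize a regression head for a given backbone width
#'
#' One hidden layer with tanh nonlinearity and a scalar output. Linear
#' merges start from all-ones weight vectors (so the initial merge is a
#' plain sum); the hidden and output layers use small seeded Gaussian
#' initialization. Antisymmetric heads keep `w_mt = -w_wt` tied and all
#' biases at zero, making every prediction an odd function of the
#' (wt, mt) ordering.
#'
#' @param spec A [head_spec()].
#' @param width Embedding width D of the backbone.
#' @param seed Seed for the weight initialization.
#' @return A `protstab_head` (untrained).
#' @export
init_head <- function(spec, width, seed = 1L) {
  fw <- feature_width(spec, width)
  abort_if(spec$merge == "outer_product" && width > spec$outer_cap,
           "outer product at width %d exceeds cap %d; use a narrower backbone",
           width, spec$outer_cap)
  params <- with_seed(seed, {
    p <- list(
      W1 = matrix(rnorm(spec$hidden * fw, sd = sqrt(1 / fw)),
                  spec$hidden, fw),
      b1 = rep(0, spec$hidden),
      W2 = rnorm(spec$hidden, sd = sqrt(1 / spec$hidden)),
      b2 = 0
    )
    if (spec$merge == "linear") {
      lw <- if (spec$source == "cls_position") 2L * width else width
      p$w_wt <- rep(1, lw)
      p$w_mt <- if (spec$antisymmetric) -p$w_wt else rep(1, lw)
    }
    p
  })
  structure(list(spec = spec, width = as.integer(width), params = params,
                 trained = FALSE, seed = as.integer(seed)),
            class = "protstab_head")
}

#' @export
print.protstab_head <- function(x, ...) {
  cat(sprintf("protstab_head: %s / %s (D=%d, hidden=%d, %s%s)\n",
              x$spec$source, x$spec$merge, x$width, x$spec$hidden,
              if (x$trained) "trained" else "untrained",
              if (x$spec$antisymmetric) ", antisymmetric" else ""))
  invisible(x)
}

# forward pass on a ready feature vector
head_forward <- function(head, features) {
  p <- head$params
  h <- tanh(as.vector(p$W1 %*% features) + p$b1)
  sum(p$W2 * h) + p$b2
}

#' Predict ddG for one wild-type/mutant pair
#'
#' Embeds both sequences with the backbone, combines them per the head's
#' specification, and applies the head network. Deterministic for fixed
#' model state and input. An untrained head refuses to predict unless
#' `allow_untrained = TRUE` (used for structural tests of the
#' antisymmetric tying) — it never silently returns an untrained output.
#'
#' @param head A `protstab_head`.
#' @param pair A [variant_pair()] or a list with `wt_seq`, `mt_seq`,
#'   `position`.
#' @param backbone A `protstab_backbone`.
#' @param allow_untrained Permit predictions from an untrained head.
#' @param cache Optional environment for embedding reuse.
#' @return ddG estimate, kcal/mol (positive = destabilizing).
#' @export
predict_head <- function(head, pair, backbone, allow_untrained = FALSE,
                         cache = NULL) {
  abort_if(!inherits(head, "protstab_head"), "not a protstab_head")
  abort_if(!head$trained && !allow_untrained,
           "head is untrained; train it or pass allow_untrained = TRUE")
  e_wt <- embed_cached(pair$wt_seq, backbone, cache)
  e_mt <- embed_cached(pair$mt_seq, backbone, cache)
  f <- combine_embeddings(head, e_wt, e_mt, pair$position)
  head_forward(head, f)
}

#' Assemble the five-head ensemble
#'
#' An ensemble holds exactly one trained head per admissible
#' specification; its prediction is the arithmetic mean of the five
#' member predictions.
#'
#' @param heads Named list of five trained `protstab_head` objects (as
#'   produced by [train_ensemble()]).
#' @return A `protstab_ensemble`.
#' @export
build_ensemble <- function(heads) {
  want <- names(five_head_specs())
  have <- vapply(want, function(nm) {
    h <- heads[[nm]]
    !is.null(h) && inherits(h, "protstab_head")
  }, TRUE)
  abort_if(any(!have), "ensemble is missing head(s): %s",
           paste(want[!have], collapse = ", "))
  structure(list(heads = heads[want]), class = "protstab_ensemble")
}

#' Predict ddG with the five-head ensemble
#'
#' @param ensemble A `protstab_ensemble`.
#' @param pair A variant pair.
#' @param backbone A `protstab_backbone`.
#' @inheritParams predict_head
#' @return The arithmetic mean of the five member predictions.
#' @export
predict_ensemble <- function(ensemble, pair, backbone,
                             allow_untrained = FALSE, cache = NULL) {
  abort_if(!inherits(ensemble, "protstab_ensemble"),
           "not a protstab_ensemble")
  preds <- vapply(ensemble$heads, predict_head, 0, pair = pair,
                  backbone = backbone, allow_untrained = allow_untrained,
                  cache = cache)
  mean(preds)
}

#' @export
print.protstab_ensemble <- function(x, ...) {
  cat("protstab_ensemble of 5 heads:\n")
  for (h in x$heads) print(h)
  invisible(x)
}
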
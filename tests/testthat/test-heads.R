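test_that("only the five admissible head combinations are accepted", {
  expect_s3_class(head_spec("position", "concatenation"), "head_spec")
  expect_s3_class(head_spec("position", "outer_product"), "head_spec")
  expect_s3_class(head_spec("position", "linear"), "head_spec")
  expect_s3_class(head_spec("cls", "linear"), "head_spec")
  expect_s3_class(head_spec("cls_position", "linear"), "head_spec")
  expect_error(head_spec("cls", "concatenation"), "inadmissible")
  expect_error(head_spec("cls", "outer_product"), "inadmissible")
  expect_error(head_spec("cls_position", "outer_product"), "inadmissible")
  expect_error(head_spec("position", "concatenation",
                         antisymmetric = TRUE), "linear")
  expect_equal(length(five_head_specs()), 5)
})

test_that("feature widths are 2D, D^2 and D/2D for several widths", {
  for (D in c(3L, 4L, 8L)) {
    expect_equal(feature_width(head_spec("position", "concatenation"), D),
                 2L * D)
    expect_equal(feature_width(head_spec("position", "outer_product"), D),
                 D^2)
    expect_equal(feature_width(head_spec("position", "linear"), D), D)
    expect_equal(feature_width(head_spec("cls", "linear"), D), D)
    expect_equal(feature_width(head_spec("cls_position", "linear"), D),
                 2L * D)
    bb <- backbone_mock(width = D, seed = 1)
    e1 <- embed_sequence("ACDEFG", bb)
    e2 <- embed_sequence("AWDEFG", bb)
    for (sp in five_head_specs())
      expect_length(combine_embeddings(sp, e1, e2, 2),
                    feature_width(sp, D))
  }
})

test_that("linear merge with identity/zero weights reproduces input rows", {
  bb <- backbone_mock(width = 6, seed = 3)
  e1 <- embed_sequence("ACDEFG", bb)
  e2 <- embed_sequence("AWDEFG", bb)
  sp <- head_spec("position", "linear")
  f <- combine_embeddings(sp, e1, e2, 2, w_wt = rep(1, 6),
                          w_mt = rep(0, 6))
  expect_equal(f, mutation_row(e1, 2))
  f2 <- combine_embeddings(sp, e1, e2, 2, w_wt = rep(0, 6),
                           w_mt = rep(1, 6))
  expect_equal(f2, mutation_row(e2, 2))
})

test_that("outer product is direction-sensitive; linear swap exchanges weights", {
  bb <- backbone_mock(width = 5, seed = 4)
  e1 <- embed_sequence("ACDEF", bb)
  e2 <- embed_sequence("AWDEF", bb)
  sp_o <- head_spec("position", "outer_product")
  expect_false(isTRUE(all.equal(combine_embeddings(sp_o, e1, e2, 2),
                                combine_embeddings(sp_o, e2, e1, 2))))
  sp_l <- head_spec("position", "linear")
  a <- runif(5); b <- runif(5)
  expect_equal(combine_embeddings(sp_l, e1, e2, 2, w_wt = a, w_mt = b),
               combine_embeddings(sp_l, e2, e1, 2, w_wt = b, w_mt = a))
})

test_that("embedding width mismatches and the outer-product cap are errors", {
  e1 <- mock_embed("ACDEF", width = 4)
  e2 <- mock_embed("AWDEF", width = 5)
  expect_error(combine_embeddings(head_spec("position", "linear"),
                                  e1, e2, 2), "width mismatch")
  sp <- head_spec("position", "outer_product", outer_cap = 3)
  e3 <- mock_embed("AWDEF", width = 4)
  expect_error(combine_embeddings(sp, e1, e3, 2), "exceeds cap")
  expect_error(init_head(sp, width = 4), "exceeds cap")
})

test_that("predictions are deterministic and untrained heads refuse", {
  bb <- backbone_mock(width = 6, seed = 1)
  head <- init_head(head_spec("position", "linear"), 6, seed = 2)
  pair <- apply_mutation("ACDEFGHIKL", "C", 2, "W")
  expect_error(predict_head(head, pair, bb), "untrained")
  p1 <- predict_head(head, pair, bb, allow_untrained = TRUE)
  p2 <- predict_head(head, pair, bb, allow_untrained = TRUE)
  expect_identical(p1, p2)
  expect_true(is.finite(p1))
})

test_that("antisymmetric-tied heads satisfy predict(a,b) = -predict(b,a)", {
  bb <- backbone_mock(width = 6, seed = 8)
  for (src in c("position", "cls", "cls_position")) {
    head <- init_head(head_spec(src, "linear", antisymmetric = TRUE),
                      6, seed = 3)
    # perturb the tied weights away from the +/-1 init, keeping the tie
    head$params$w_wt <- with_seed(4, rnorm(length(head$params$w_wt)))
    head$params$w_mt <- -head$params$w_wt
    devs <- with_seed(11, replicate(100, {
      s <- paste(sample(AA_ALPHABET, 12, replace = TRUE), collapse = "")
      pos <- sample.int(12, 1)
      wt <- substr(s, pos, pos)
      mt <- sample(setdiff(AA_ALPHABET, wt), 1)
      vp <- apply_mutation(s, wt, pos, mt)
      rev <- list(wt_seq = vp$mt_seq, mt_seq = vp$wt_seq, position = pos)
      abs(predict_head(head, vp, bb, allow_untrained = TRUE) +
            predict_head(head, rev, bb, allow_untrained = TRUE))
    }))
    expect_true(all(devs < 1e-6))
  }
})

test_that("ensemble prediction is the member mean, invariant to order", {
  const_head <- function(value) {
    h <- init_head(head_spec("position", "linear"), 4, seed = 1)
    h$params$W1 <- h$params$W1 * 0
    h$params$W2 <- h$params$W2 * 0
    h$params$b2 <- value
    h$trained <- TRUE
    h
  }
  vals <- c(1, 2, 3, 4, 5)
  heads <- setNames(lapply(vals, const_head), names(five_head_specs()))
  ens <- build_ensemble(heads)
  bb <- backbone_mock(width = 4, seed = 1)
  pair <- apply_mutation("ACDEF", "C", 2, "W")
  expect_equal(predict_ensemble(ens, pair, bb), 3.0)

  heads0 <- setNames(lapply(c(0, 0, 0, 0, 0), const_head),
                     names(five_head_specs()))
  expect_equal(predict_ensemble(build_ensemble(heads0), pair, bb), 0)
  heads2 <- setNames(lapply(c(-1, 1, -1, 1, 0), const_head),
                     names(five_head_specs()))
  expect_equal(predict_ensemble(build_ensemble(heads2), pair, bb), 0)

  perm <- heads[c(3, 1, 5, 2, 4)]
  expect_equal(predict_ensemble(build_ensemble(perm), pair, bb), 3.0)
})

test_that("a missing ensemble member is reported by name", {
  heads <- setNames(vector("list", 5), names(five_head_specs()))
  heads$position_concat <- init_head(head_spec("position", "concatenation"),
                                     4, seed = 1)
  expect_error(build_ensemble(heads), "position_outer")
})
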
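test_that("config validation rejects inconsistent settings", {
  expect_s3_class(tiny_config(), "fold_config")
  expect_error(model_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(model_config(max_len = 100, unet_depth = 3), "multiple of 2")
  expect_error(model_config(embed_dim = 0), "positive")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("model construction is deterministic in the seed", {
  suppressMessages({
    n1 <- build_model(tiny_config(seed = 9))
    n2 <- build_model(tiny_config(seed = 9))
    n3 <- build_model(tiny_config(seed = 10))
  })
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, n3$params))
})

test_that("forward produces per-sequence L x L scores and enforces max length", {
  net <- suppressMessages(build_model(tiny_config()))
  seqs <- list(random_rna(32, "a"), random_rna(17, "b"))
  Ms <- forward_scores(net, seqs)
  expect_equal(dim(Ms[[1]]), c(32, 32))
  expect_equal(dim(Ms[[2]]), c(17, 17))
  expect_equal(symmetrize(Ms[[1]]), t(symmetrize(Ms[[1]])))
  expect_error(forward_scores(net, random_rna(80, "long")), "long")
})

test_that("scores at real positions do not depend on the padding length", {
  net <- suppressMessages(build_model(tiny_config()))
  s <- random_rna(13, "p")
  M1 <- rowfold:::forward_single(net, s, Lp = 14)$M
  M2 <- rowfold:::forward_single(net, s, Lp = 20)$M
  expect_equal(M1, M2, tolerance = 1e-8)
})

test_that("network gradients match finite differences", {
  set.seed(41)
  net <- suppressMessages(build_model(tiny_config(seed = 3)))
  s <- make_hairpin(3, 4, id = "g")
  Sh <- modify_label(s$structure)
  loss_of <- function(n) {
    M <- rowfold:::forward_single(n, s$seq)$M
    rowfold:::wce_scores_grad(symmetrize(M), Sh)$loss
  }
  fwd <- rowfold:::forward_single(net, s$seq)
  lg <- rowfold:::wce_scores_grad(symmetrize(fwd$M), Sh)
  grads <- rowfold:::backward_single(net, fwd, (lg$grad + t(lg$grad)) / 2)
  eps <- 1e-5
  for (nm in c("E", "L1.Wq", "L1.Wo", "L1.W1", "L1.ln1_g", "lnf_g",
               "enc0_W", "down1_W", "up1_W", "head_W")) {
    p <- net$params[[nm]]
    for (i in sample(length(p), 2)) {
      n1 <- net; n1$params[[nm]][i] <- p[i] + eps
      n2 <- net; n2$params[[nm]][i] <- p[i] - eps
      num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})

test_that("predictions are valid regardless of training state", {
  net <- suppressMessages(build_model(tiny_config(seed = 5)))
  set.seed(42)
  seqs <- lapply(1:50, function(k) random_rna(sample(8:40, 1), paste0("s", k)))
  preds <- predict_structures(net, seqs)
  expect_length(preds, 50L)
  for (P in preds) expect_length(audit_validity(P), 0L)
  expect_equal(predict_structures(net, list()), list())
  expect_equal(predict(net, seqs[1:2]), preds[1:2])
})

test_that("one epoch of training reduces the loss on a small toy set", {
  samples <- make_fixture_dataset(60, stem_range = c(3, 6),
                                  loop_range = c(3, 6), seed = 43)
  net <- suppressMessages(build_model(tiny_config(seed = 4)))
  l0 <- rowfold:::evaluate_loss(net, samples)
  net <- train_model(net, samples, epochs = 1, lr = 2e-3, seed = 43)
  expect_lt(rowfold:::evaluate_loss(net, samples), l0)
  expect_length(net$trace, 1L)
  expect_error(train_model(net, list()), "empty")
})

test_that("training resumes deterministically from a checkpoint", {
  samples <- make_fixture_dataset(20, stem_range = c(3, 5),
                                  loop_range = c(3, 5), seed = 44)
  base <- suppressMessages(build_model(tiny_config(seed = 6)))
  full <- train_model(base, samples, epochs = 2, lr = 1e-3, seed = 44)

  ckpt <- withr::local_tempfile(fileext = ".rds")
  half <- train_model(base, samples, epochs = 1, lr = 1e-3, seed = 44)
  save_checkpoint(half, ckpt)
  resumed <- train_model(load_checkpoint(ckpt), samples, epochs = 1,
                         lr = 1e-3, seed = 44)
  expect_equal(resumed$trace, full$trace, tolerance = 1e-12)
  expect_equal(resumed$params, full$params, tolerance = 1e-12)
})
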
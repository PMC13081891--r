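# PIP computation, BFDR gene selection and report files

test_that("PIPs equal direct draw frequencies (recount oracle)", {
  set.seed(1)
  p <- 4; m <- 2; S <- 200
  I <- matrix(rbinom(S * p, 1, 0.6), S, p)
  U <- array(rbinom(p * m * S, 1, 0.5), c(p, m, S))
  b <- array(rnorm(p * m * S), c(p, m, S))
  B <- array(0, c(p, m, S))
  for (s in seq_len(S)) B[, , s] <- b[, , s] * U[, , s] * I[s, ]
  L <- array(rnorm(3 * m * S), c(3, m, S))
  dr <- fake_draws(B, I, U, L)
  pips <- compute_pips(dr, align = FALSE)
  # independent recount
  for (j in seq_len(p)) {
    for (l in seq_len(m))
      expect_identical(pips$pip_factor[j, l],
                       mean(I[, j] == 1 & U[j, l, ] == 1))
    expect_identical(pips$pip_omnibus[j],
                     mean(vapply(seq_len(S), function(s)
                       I[s, j] == 1 && any(U[j, , s] == 1), logical(1))))
  }
  # union bound holds per gene
  expect_true(all(pips$pip_omnibus >= apply(pips$pip_factor, 1, max)))
})

test_that("degenerate indicator patterns give the expected PIPs", {
  p <- 2; m <- 2; S <- 120
  # all indicators on in every draw
  I <- matrix(1L, S, p)
  U <- array(1, c(p, m, S))
  B <- array(1, c(p, m, S))
  L <- array(0.5, c(3, m, S))
  pips <- compute_pips(fake_draws(B, I, U, L), align = FALSE)
  expect_true(all(pips$pip_factor == 1) && all(pips$pip_omnibus == 1))
  # factor 1 active in one half of draws, factor 2 in the other half
  U2 <- array(0, c(1, 2, S)); B2 <- array(0, c(1, 2, S))
  U2[1, 1, 1:(S / 2)] <- 1; B2[1, 1, 1:(S / 2)] <- 1
  U2[1, 2, (S / 2 + 1):S] <- 1; B2[1, 2, (S / 2 + 1):S] <- 1
  pips2 <- compute_pips(fake_draws(B2, matrix(1L, S, 1), U2,
                                   array(0.5, c(3, 2, S))), align = FALSE)
  expect_equal(unname(pips2$pip_factor[1, ]), c(0.5, 0.5))
  expect_equal(pips2$pip_omnibus[1], 1.0)
})

test_that("BFDR selection matches the exhaustive threshold scan", {
  sel <- bfdr_select(c(0.99, 0.95, 0.60, 0.10), alpha = 0.05)
  expect_identical(sel$selected_idx, 1:2)
  expect_equal(sel$bfdr_at_threshold, 0.03)
  expect_equal(sel$threshold, 0.95)
  # adding the next gene would breach the level
  expect_equal(mean(1 - c(0.99, 0.95, 0.60)), 0.1533, tolerance = 1e-3)

  sel_all <- bfdr_select(rep(1, 5), alpha = 0.05)
  expect_length(sel_all$selected_genes, 5)
  expect_equal(sel_all$bfdr_at_threshold, 0)

  sel_none <- bfdr_select(c(0.8, 0.7), alpha = 0.001)
  expect_length(sel_none$selected_genes, 0)
  expect_true(is.na(sel_none$threshold))
  expect_error(bfdr_select(c(0.5, 1.2)), "0, 1")
})

test_that("BFDR operator invariants hold on random PIP vectors", {
  set.seed(2)
  for (rep in 1:200) {
    pips <- runif(sample(3:40, 1))^sample(1:3, 1)
    # monotonicity: BFDR over {PIP >= z} is non-increasing in z
    zs <- sort(unique(pips))
    bf <- vapply(zs, function(z) mean(1 - pips[pips >= z]), 0)
    expect_true(all(diff(bf) <= 1e-12))
    # nesting: a stricter level selects a subset
    s1 <- bfdr_select(pips, alpha = 0.05)
    s2 <- bfdr_select(pips, alpha = 0.2)
    expect_true(all(s1$selected_idx %in% s2$selected_idx))
    # selected set is exactly a PIP threshold set
    if (length(s2$selected_idx) > 0)
      expect_setequal(s2$selected_idx, which(pips >= s2$threshold))
  }
})

test_that("reports are written, sorted and re-readable", {
  set.seed(3)
  p <- 3; m <- 2; S <- 150
  I <- matrix(rbinom(S * p, 1, 0.9), S, p)
  U <- array(rbinom(p * m * S, 1, 0.9), c(p, m, S))
  B <- array(rnorm(p * m * S), c(p, m, S))
  for (s in seq_len(S)) B[, , s] <- B[, , s] * U[, , s] * I[s, ]
  L <- array(rnorm(5 * m * S, sd = 0.4), c(5, m, S))
  dr <- fake_draws(B, I, U, L)
  pips <- compute_pips(dr)
  sel <- bfdr_select(pips, alpha = 0.2)
  out <- tempfile()
  report(sel, dr, out)
  genes <- read.delim(file.path(out, "genes.tsv"))
  expect_identical(genes$gene, dr$gene_ids)
  expect_equal(genes$pip_omnibus, unname(sel$pip_omnibus))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$n_selected, length(sel$selected_genes))
  # loading tables sorted by |posterior mean| descending
  lt <- read.delim(file.path(out, "loadings_factor1.tsv"))
  expect_identical(order(-abs(lt$loading)), seq_len(nrow(lt)))

  # empty selection still writes a valid header-only table
  dr0 <- fake_draws(array(0, c(2, 1, S)), matrix(0L, S, 2),
                    array(0, c(2, 1, S)), array(0.1, c(3, 1, S)))
  sel0 <- bfdr_select(compute_pips(dr0), alpha = 0.05)
  out0 <- tempfile()
  report(sel0, dr0, out0)
  g0 <- read.delim(file.path(out0, "genes.tsv"))
  expect_identical(nrow(g0), 2L) # all genes listed, none selected
  expect_true(all(!g0$selected))
})
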
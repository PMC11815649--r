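stage_names <- function(n) paste0("s", seq_len(n))

protein_tbl <- function(mat, proteins = sprintf("P%02d", seq_len(nrow(mat)))) {
  out <- tibble::tibble(protein = proteins)
  for (j in seq_len(ncol(mat))) out[[paste0("s", j)]] <- mat[, j]
  out
}

test_that("razor assignment credits shared peptides to richer proteins", {
  psms <- tibble::tibble(
    peptide = c("a", "b", "c", "d", "e", "e"),
    protein = c("P1", "P1", "P1", "P2", "P1;P2", "P1;P2")
  )
  asg <- assign_peptides_to_proteins(psms)
  expect_equal(asg$protein[asg$peptide == "e"], "P1")  # 3 unique vs 1
  expect_true(asg$shared[asg$peptide == "e"])
  expect_equal(asg$protein[asg$peptide == "a"], "P1")
  expect_false(asg$shared[asg$peptide == "a"])

  # tie: equal unique counts -> lexicographically first, flagged
  tie <- assign_peptides_to_proteins(tibble::tibble(
    peptide = c("u1", "u2", "v1", "v2", "s"),
    protein = c("PB", "PB", "PA", "PA", "PA;PB")
  ))
  expect_equal(tie$protein[tie$peptide == "s"], "PA")
  expect_true(tie$tie[tie$peptide == "s"])

  expect_error(assign_peptides_to_proteins(tibble::tibble(
    peptide = "x", protein = "")), "no candidate")
})

test_that("anchor normalization equalizes anchor signal across stages", {
  quant <- tibble::tibble(
    peptide = c("a1", "a2", "p1"),
    anchor = c(TRUE, TRUE, FALSE),
    s1 = c(60, 40, 10), s2 = c(120, 80, 10)
  )
  norm <- normalize_to_anchor(quant)
  # anchor column sums [100, 200] -> scale to common mean 150
  expect_equal(sum(norm$s1[norm$anchor]), 150)
  expect_equal(sum(norm$s2[norm$anchor]), 150)
  # non-anchor scaled by the same factors
  expect_equal(norm$s1[3], 15)
  expect_equal(norm$s2[3], 7.5)

  # fixed point: already-constant anchors leave the matrix unchanged
  stable <- normalize_to_anchor(norm)
  expect_equal(as.data.frame(stable), as.data.frame(norm), tolerance = 1e-12)

  # zero anchor signal in a column is rejected
  zq <- quant
  zq$s2[zq$anchor] <- 0
  expect_error(normalize_to_anchor(zq), "s2")
  expect_error(normalize_to_anchor(quant[!quant$anchor, ]), "No anchor")
})

test_that("anchor normalization removes acquisition drift", {
  drift <- seq(1, 2.5, length.out = 9)
  tc <- simulate_timecourse(n_proteins = 60, noise_sd = 0.05,
                            stage_efficiency = drift, seed = 12)
  norm <- normalize_to_anchor(tc$quant)
  prot <- rollup_proteins(norm)
  # constant-archetype proteins should be flat again after normalization
  const <- tc$proteins$protein[tc$proteins$archetype == "constant"]
  m <- as.matrix(prot[prot$protein %in% const, stage_names(9)])
  rel_spread <- apply(m / rowMeans(m), 1, function(x) diff(range(x)))
  expect_lt(stats::median(rel_spread), 0.15)
})

test_that("protein roll-up takes the median of mean-scaled peptides", {
  # single peptide: protein profile equals the peptide profile
  q1 <- tibble::tibble(peptide = "p", protein = "P", s1 = 2, s2 = 4, s3 = 6)
  r1 <- rollup_proteins(q1)
  expect_equal(as.numeric(r1[1, stage_names(3)]), c(2, 4, 6))

  # three identical profiles give the same profile
  q3 <- tibble::tibble(peptide = c("p1", "p2", "p3"), protein = "P",
                       s1 = 2, s2 = 4, s3 = 6)
  r3 <- rollup_proteins(q3)
  expect_equal(as.numeric(r3[1, stage_names(3)]) / sum(r3[1, stage_names(3)]),
               c(2, 4, 6) / 12)

  # the median suppresses one outlier profile (brute-force oracle)
  q <- tibble::tibble(
    peptide = c("p1", "p2", "p3"), protein = "P",
    s1 = c(1, 1, 10), s2 = c(2, 2, 1), s3 = c(3, 3, 1)
  )
  r <- rollup_proteins(q)
  m <- as.matrix(q[, stage_names(3)])
  scaled <- m / rowMeans(m)
  oracle <- apply(scaled, 2, median)
  oracle <- oracle * sum(m) / sum(oracle)
  expect_equal(as.numeric(r[1, stage_names(3)]), unname(oracle))

  # permutation invariance in peptide order
  r_perm <- rollup_proteins(q[c(3, 1, 2), ])
  expect_equal(as.data.frame(r_perm), as.data.frame(r))

  # zero-signal proteins are dropped with a message
  qz <- dplyr::bind_rows(q, tibble::tibble(peptide = "z", protein = "Z",
                                           s1 = 0, s2 = 0, s3 = 0))
  expect_message(rz <- rollup_proteins(qz), "dropped")
  expect_false("Z" %in% rz$protein)
})

test_that("hierarchical k-means recovers structure deterministically", {
  set.seed(4)
  arch <- rbind(rep(1, 6), seq(1, 3, length.out = 6), seq(3, 1, length.out = 6))
  mat <- arch[rep(1:3, each = 12), ] * exp(matrix(rnorm(36 * 6, 0, 0.03), 36))
  tbl <- protein_tbl(mat)

  f1 <- hkmeans_cluster(tbl, k = 1)
  expect_equal(unique(tidy(f1)$cluster), 1L)

  fit <- hkmeans_cluster(tbl, k = 3)
  expect_equal(sort(unique(tidy(fit)$cluster)), 1:3)
  expect_equal(nrow(tidy(fit)), 36)
  truth <- rep(1:3, each = 12)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(tidy(fit)$cluster, truth), 1)

  # row order changes labels at most by permutation
  perm <- sample(36)
  fit2 <- hkmeans_cluster(tbl[perm, ], k = 3)
  expect_equal(mclust::adjustedRandIndex(
    tidy(fit2)$cluster, truth[perm]), 1)

  expect_error(hkmeans_cluster(tbl, k = 40), "exceeds")
  gl <- glance(fit)
  expect_equal(gl$k, 3)
})

test_that("two-pass reclustering isolates one cluster then reclusters", {
  set.seed(5)
  arch <- rbind(seq(3, 1, length.out = 6), rep(1, 6),
                seq(1, 3, length.out = 6), c(1, 2, 3, 3, 2, 1))
  mat <- arch[rep(1:4, each = 10), ] * exp(matrix(rnorm(40 * 6, 0, 0.03), 40))
  tbl <- protein_tbl(mat)
  out <- recluster_schedule(tbl, k_first = 4, k_second = 3)
  expect_equal(nrow(out), 40)
  expect_true(any(out$cluster == 0))
  expect_equal(sort(unique(out$cluster)), 0:3)
  # default isolation rule picks the most strongly decreasing cluster
  iso <- out$protein[out$cluster == 0]
  expect_true(all(iso %in% tbl$protein[1:10]))
})

test_that("fold-change summaries classify and partition correctly", {
  tbl <- protein_tbl(rbind(
    c(4, 2, 1),    # log2(first/last) = 2 -> decreasing
    c(1, 1, 1),    # 0 -> within
    c(1, 2, 8),    # -3 -> increasing
    c(1.5, 1, 1)   # 0.58 -> within at twofold
  ))
  fc <- fold_change_summary(tbl, threshold_fold = 2)
  td <- tidy(fc)
  expect_equal(td$log2_first_last, c(2, 0, -3, log2(1.5)))
  expect_equal(td$class, c("decreasing", "within", "increasing", "within"))
  expect_equal(sum(fc$fractions), 1)
  gl <- glance(fc)
  expect_equal(gl$frac_decreasing + gl$frac_increasing + gl$frac_within, 1)

  # zeros floored at half the smallest positive value and flagged
  tblz <- protein_tbl(rbind(c(4, 2, 0), c(1, 1, 1)))
  fcz <- fold_change_summary(tblz)
  expect_true(tidy(fcz)$floored[1])
  expect_equal(tidy(fcz)$log2_first_last[1], log2(4 / 0.5))

  expect_error(fold_change_summary(tbl, threshold_fold = 1), "> 1")

  # a simulated 7% decreasing class is recovered exactly without noise
  n <- 200; n_dec <- 14
  m <- rbind(matrix(rep(c(4, 2, 1), n_dec), ncol = 3, byrow = TRUE),
             matrix(1, n - n_dec, 3))
  fc7 <- fold_change_summary(protein_tbl(m))
  expect_equal(unname(fc7$fractions["decreasing"]), 0.07)
})

test_that("orthogroup representatives maximize quantified peptides", {
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG1", "OG1", "OG2", "OG3"),
    organism = c("fly", "fly", "frog", "fly", "frog"),
    protein_id = c("F1", "F2", "X1", "F3", "X9")
  )
  counts <- tibble::tibble(
    protein_id = c("F1", "F2", "X1", "F3"),
    n_peptides = c(5, 2, 4, 1)
  )
  expect_message(rep_tab <- orthogroup_representatives(og, counts), "ignored")
  expect_equal(rep_tab$protein_id[rep_tab$orthogroup_id == "OG1" &
                                    rep_tab$organism == "fly"], "F1")
  expect_equal(rep_tab$protein_id[rep_tab$orthogroup_id == "OG2"], "F3")
  expect_false("X9" %in% rep_tab$protein_id)

  # tie-break lexicographic and flagged
  tie <- orthogroup_representatives(
    og[1:2, ], tibble::tibble(protein_id = c("F1", "F2"), n_peptides = c(3, 3)))
  expect_equal(tie$protein_id, "F1")
  expect_true(tie$tie)

  # three organisms x synthetic orthogroups: set-intersection oracle
  set.seed(10)
  orgs <- c("fly", "frog", "squirt")
  og_big <- tidyr::expand_grid(orthogroup_id = paste0("OG", 1:20),
                               organism = orgs) |>
    dplyr::filter(stats::runif(dplyr::n()) > 0.3) |>
    dplyr::mutate(protein_id = paste0(.data$organism, "_", .data$orthogroup_id))
  cnt <- tibble::tibble(protein_id = og_big$protein_id,
                        n_peptides = sample(1:9, nrow(og_big), replace = TRUE))
  rep_big <- orthogroup_representatives(og_big, cnt)
  # one representative per (orthogroup, organism) present
  oracle <- unique(og_big[, c("orthogroup_id", "organism")])
  expect_equal(nrow(rep_big), nrow(oracle))
  ov <- table(rep_big$orthogroup_id)
  ov_oracle <- table(oracle$orthogroup_id)
  expect_equal(as.vector(ov[names(ov_oracle)]), as.vector(ov_oracle))
})
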
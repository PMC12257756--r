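test_that("pedigree reading validates, normalizes and sorts records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "C,A,B", "A,0,0", "B,NA,"), f)
  ped <- read_pedigree(f)
  expect_equal(ped$id, c("A", "B", "C"))
  expect_equal(ped$sire, c(0L, 0L, 1L))
  expect_equal(ped$F, c(0, 0, 0))

  # writer round-trip preserves content and is topologically sorted
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f2)
  ped2 <- read_pedigree(f2)
  expect_identical(as.data.frame(ped), as.data.frame(ped2))

  writeLines(c("animal,sire,dam", "A,0,0", "A,0,0"), f)
  expect_error(read_pedigree(f), "duplicate")
  writeLines(c("animal,sire,dam", "A,A,0"), f)
  expect_error(read_pedigree(f), "own parent")
  writeLines(c("animal,sire,dam", "A,B,0", "B,A,0"), f)
  expect_error(read_pedigree(f), "cycle")
})

test_that("unlisted parents are auto-added as founders", {
  ped <- new_pedigree("X", "S1", "D1")
  expect_setequal(ped$id, c("S1", "D1", "X"))
  expect_equal(sum(ped$sire == 0L & ped$dam == 0L), 2L)
})

test_that("relationship matrix matches closed forms on founders and a trio", {
  ped <- new_pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  A <- relationship_matrix(ped)
  expect_equal(unname(A[c("S", "D"), c("S", "D")]), diag(2))
  expect_equal(A["O", "S"], 0.5)
  expect_equal(A["O", "D"], 0.5)
  expect_equal(A["O", "O"], 1)
})

test_that("relationship matrix agrees with the gene-dropping oracle", {
  ped <- random_pedigree()
  A <- relationship_matrix(ped)
  n <- length(ped$id)
  set.seed(42)
  pairs <- cbind(sample(n, 30, replace = TRUE), sample(n, 30, replace = TRUE))
  pairs <- rbind(pairs, cbind(1:8, 1:8), cbind(n - 0:7, n - 0:7))
  gd <- gene_drop_a(ped, pairs, ndrop = 2e5)
  for (r in seq_len(nrow(pairs))) {
    expect_lt(abs(A[pairs[r, 1], pairs[r, 2]] - gd[r, "est"]),
              3 * gd[r, "se"] + 1e-12)
  }
})

test_that("A inverse obeys Henderson closed forms and inverts A", {
  ped <- new_pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  Ai <- a_inverse(ped)
  expect_equal(Ai["O", "O"], 2)
  expect_equal(Ai["O", "S"], -1)
  expect_equal(Ai["S", "S"], 1.5)

  founders <- new_pedigree(letters[1:4], rep(NA, 4), rep(NA, 4))
  expect_equal(as.matrix(a_inverse(founders)), diag(4), ignore_attr = TRUE)

  ped50 <- random_pedigree()
  A <- relationship_matrix(ped50)
  Ai <- a_inverse(ped50)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(length(ped50$id)))), 1e-8)
})

test_that("inbreeding and mean inbreeding match the recursive kinship oracle", {
  # offspring of a full-sib mating is 25% inbred
  ped <- new_pedigree(c("S", "D", "A", "B", "X"),
                      c(NA, NA, "S", "S", "A"),
                      c(NA, NA, "D", "D", "B"))
  expect_equal(mean_inbreeding(ped, "X"), 0.25)
  expect_equal(mean_inbreeding(ped, c("S", "D")), 0)
  expect_error(mean_inbreeding(ped, "nope"), "unknown")
  expect_error(mean_inbreeding(ped, character(0)), "empty")

  ped50 <- random_pedigree(n_founders = 8, n_offspring = 40, seed = 11)
  phi <- kinship_oracle(ped50)
  expect_equal(ped50$F, 2 * diag(phi) - 1, tolerance = 1e-12)
  sub <- sample(ped50$id, 12)
  expect_equal(mean_inbreeding(ped50, sub),
               mean((2 * diag(phi) - 1)[match(sub, ped50$id)]))
})

test_that("A is symmetric PSD with diagonal 1 + F", {
  ped <- random_pedigree(n_founders = 8, n_offspring = 40, seed = 23)
  A <- relationship_matrix(ped)
  expect_equal(A, t(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(unname(diag(A)), 1 + ped$F)
  expect_true(all(A >= 0 & A <= 2))
})

test_that("pruning keeps anchors plus ancestors within the depth cut", {
  chain <- new_pedigree(c("a", "b", "c", "d", "e"),
                        c(NA, "a", "b", "c", "d"), rep(NA, 5))
  expect_equal(prune_to_generations(chain, "e", 0)$id, "e")
  expect_equal(length(prune_to_generations(chain, "e", 3)$id), 4L)
  expect_setequal(prune_to_generations(chain, "e", 10)$id, chain$id)

  # A-entries among animals whose full ancestry is retained are unchanged
  ped <- random_pedigree(n_founders = 8, n_offspring = 30, seed = 5)
  A <- relationship_matrix(ped)
  pruned <- prune_to_generations(ped, ped$id, 99)
  A2 <- relationship_matrix(pruned)
  expect_equal(A2[ped$id, ped$id], A)
})
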
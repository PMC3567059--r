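mk_roster <- function(...) {
  rows <- list(...)
  data.frame(id = vapply(rows, `[[`, "", 1),
             surname_paternal = vapply(rows, `[[`, "", 2),
             surname_maternal = vapply(rows, `[[`, "", 3),
             classroom = "C1", grade = "1", stringsAsFactors = FALSE)
}
mk_noms <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(subject = character(0), target = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  data.frame(subject = vapply(rows, `[[`, "", 1),
             target = vapply(rows, `[[`, "", 2),
             relation = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("sibling rule needs one nomination plus both surnames", {
  roster <- mk_roster(c("A", "Garcia", "Pech"), c("B", "Garcia", "Pech"),
                      c("C", "Garcia", "May"))
  kin <- infer_kinship(roster, mk_noms(c("A", "B", "sibling"),
                                       c("A", "C", "sibling")))
  expect_equal(kin$sibling["A", "B"], 1L)
  expect_equal(kin$sibling["B", "A"], 1L)
  # C shares one surname but not both: not a sibling, and not a cousin
  # without a cousin nomination
  expect_equal(kin$sibling["A", "C"], 0L)
  expect_equal(kin$cousin["A", "C"], 0L)

  # surname comparison is case/whitespace insensitive
  roster2 <- mk_roster(c("A", " garcia ", "PECH"), c("B", "Garcia", "Pech"))
  kin2 <- infer_kinship(roster2, mk_noms(c("B", "A", "sibling")))
  expect_equal(kin2$sibling["A", "B"], 1L)
})

test_that("kinship closure is transitive for siblings and lifts cousins", {
  roster <- mk_roster(c("A", "Garcia", "Pech"), c("B", "Garcia", "Pech"),
                      c("C", "Garcia", "Pech"), c("D", "Garcia", "May"))
  noms <- mk_noms(c("A", "B", "sibling"), c("B", "C", "sibling"),
                  c("D", "B", "cousin"))
  kin <- infer_kinship(roster, noms)
  expect_equal(kin$sibling["A", "C"], 1L)        # transitivity
  expect_equal(kin$cousin["D", "A"], 1L)         # cousin of a sibling
  expect_equal(kin$cousin["D", "C"], 1L)
  # sibling precedence: no pair is both
  expect_true(all(kin$sibling + kin$cousin <= 1))

  # sibling relation is an equivalence relation on its support
  sib <- kin$sibling
  expect_true(all(sib == t(sib)))
  expect_true(all(diag(sib) == 0))
  reach <- (sib %*% sib > 0) * 1L; diag(reach) <- 0L
  expect_true(all(reach <= sib))
})

test_that("friendship is bilateral with kinship folded in", {
  roster <- mk_roster(c("A", "Garcia", "Pech"), c("B", "Canul", "May"),
                      c("C", "Uc", "Chi"), c("D", "Garcia", "Pech"))
  noms <- mk_noms(c("A", "B", "friend"), c("B", "A", "friend"),
                  c("A", "C", "friend"),            # unreciprocated
                  c("A", "D", "sibling"))
  m <- build_matrices(roster, noms)
  expect_equal(m$friendship["A", "B"], 1L)
  expect_equal(m$friendship["A", "C"], 0L)
  expect_equal(m$friendship["A", "D"], 1L)   # siblings are friends
  expect_true(all(m$friendship == t(m$friendship)))
  expect_true(all(m$kinship <= m$friendship))  # kinship subset of friendship
})

test_that("enmity is bilateral and friend/enemy conflicts are surfaced", {
  roster <- mk_roster(c("A", "Garcia", "Pech"), c("B", "Canul", "May"))
  noms <- mk_noms(c("A", "B", "enemy"), c("B", "A", "enemy"),
                  c("A", "B", "friend"), c("B", "A", "friend"))
  expect_warning(m <- build_matrices(roster, noms), "simultaneously")
  expect_equal(m$enmity["A", "B"], 1L)
  expect_equal(m$friendship["A", "B"], 1L)
  expect_equal(nrow(m$conflicts), 1L)
})

test_that("unknown ids in nominations raise a located error", {
  roster <- mk_roster(c("A", "Garcia", "Pech"))
  expect_error(build_matrices(roster, mk_noms(c("A", "Z", "friend"))),
               "row 1")
})

test_that("pipeline output matrices are symmetric, zero-diagonal, idempotent", {
  s <- synthetic_roster(80, 4, family_rate = 0.2, seed = 17)
  m1 <- suppressWarnings(build_matrices(s$roster, s$nominations))
  for (nm in c("friendship", "enmity", "kinship")) {
    expect_true(all(m1[[nm]] == t(m1[[nm]])))
    expect_true(all(diag(m1[[nm]]) == 0))
  }
  m2 <- suppressWarnings(build_matrices(s$roster, s$nominations))
  expect_identical(m1$friendship, m2$friendship)
  expect_identical(m1$enmity, m2$enmity)
})

test_that("planted families are recovered as friendships", {
  s <- synthetic_roster(120, 6, family_rate = 0.3, seed = 23)
  m <- suppressWarnings(build_matrices(s$roster, s$nominations))
  for (r in seq_len(nrow(s$families))) {
    a <- s$families$id_a[r]; b <- s$families$id_b[r]
    expect_equal(m$kinship[a, b], 1L,
                 label = paste("kinship", a, b, s$families$type[r]))
    expect_equal(m$friendship[a, b], 1L)
  }
  # planted sibling pairs land in the sibling matrix specifically
  sibs <- s$families[s$families$type == "sibling", ]
  for (r in seq_len(nrow(sibs)))
    expect_equal(m$sibling[sibs$id_a[r], sibs$id_b[r]], 1L)
})

test_that("reciprocity endpoints behave as designed", {
  s1 <- synthetic_roster(40, 2, family_rate = 0, reciprocity = 1,
                         friend_mean = 3, enemy_mean = 0, seed = 31)
  m1 <- build_matrices(s1$roster, s1$nominations)
  pairs <- unique(t(apply(
    as.matrix(s1$nominations[s1$nominations$relation == "friend",
                             c("subject", "target")]), 1, sort)))
  expect_equal(sum(m1$friendship) / 2, nrow(pairs))

  s0 <- synthetic_roster(40, 2, family_rate = 0, reciprocity = 0,
                         friend_mean = 3, enemy_mean = 0, seed = 32)
  m0 <- build_matrices(s0$roster, s0$nominations)
  expect_equal(sum(m0$friendship), 0)
})

test_that("roster and nomination CSVs round-trip through the readers", {
  s <- synthetic_roster(30, 2, seed = 41)
  fr <- tempfile(fileext = ".csv"); fn <- tempfile(fileext = ".csv")
  write.csv(s$roster, fr, row.names = FALSE)
  write.csv(s$nominations, fn, row.names = FALSE)
  expect_equal(read_roster(fr)$id, s$roster$id)
  expect_equal(nrow(read_nominations(fn)), nrow(s$nominations))
  unlink(c(fr, fn))
})
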
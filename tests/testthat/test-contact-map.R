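test_that("detection thresholds and sequence separation are honoured", {
  # two residues with closest heavy atoms at 0.44 nm; CA atoms further apart
  mk <- function(resno, shift) {
    data.frame(chain = "A", resno = resno, resid = "ALA",
               elety = c("CA", "CB"), elesym = "C",
               x = c(0, 0.2) + shift, y = 0, z = 0)
  }
  s <- Structure(rbind(mk(1, 0), mk(6, 0.64)))   # CB(1)-CA(6) gap = 0.44
  hits <- detectContacts(s, "all_atom", cutoff = 0.45, min_seq_sep = 4)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$res_i, 1)
  expect_equal(hits$d_ca, 0.64)                  # annotated with CA distance
  none <- detectContacts(s, "all_atom", cutoff = 0.43, min_seq_sep = 4)
  expect_equal(nrow(none), 0)

  # adjacent residues are excluded at any distance
  s2 <- Structure(rbind(mk(1, 0), mk(2, 0.3)))
  expect_equal(nrow(detectContacts(s2, "all_atom", 0.45, 1)), 1)
  expect_equal(nrow(detectContacts(s2, "all_atom", 0.45, 2)), 0)
})

test_that("detection equals a brute-force pair scan on the toy", {
  toy <- toyFixture()
  for (mode in c("ca_cutoff", "all_atom")) {
    got <- detectContacts(toy$open, mode, cutoff = 0.8, min_seq_sep = 4)
    ca <- caCoords(toy$open)
    n <- nrow(ca)
    brute <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (j - i < 4) next
        if (sqrt(sum((ca[i, ] - ca[j, ])^2)) <= 0.8) {
          brute[[length(brute) + 1]] <- c(i, j)
        }
      }
    }
    brute <- do.call(rbind, brute)
    expect_equal(nrow(got), nrow(brute))
    expect_equal(unname(as.matrix(got[, 1:2])), unname(brute))
  }
})

test_that("the 1.5x distance-ratio rule is strict at the boundary", {
  # hand-built pair sets exercised through CA-only structures:
  # residues 1-5..; pair (1,5) present only in closed
  mkCa <- function(d15_x) {
    xyz <- rbind(c(0, 0, 0), c(0.38, 0.3, 0), c(0.76, 0, 0),
                 c(1.14, 0.3, 0), c(d15_x, 0, 0))
    Structure(data.frame(chain = "A", resno = 1:5, resid = "GLY",
                         elety = "CA", elesym = "C",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  }
  closed <- mkCa(0.7)    # d_closed(1,5) = 0.7 exactly
  d_closed <- caDistance(closed, 1, 5)

  # strictly beyond ratio*d_closed -> closed-specific
  open_far <- mkCa(1.5 * 0.7 + 0.3)
  cm <- classifyContacts(open_far, closed, "ca_cutoff", cutoff = 0.8,
                         min_seq_sep = 4)
  expect_equal(cm$class[cm$res_i == 1 & cm$res_j == 5], "closed_specific")

  # exactly at the ratio -> discarded (strict inequality)
  open_at <- mkCa(1.5 * d_closed)
  d_open <- caDistance(open_at, 1, 5)
  expect_equal(d_open, 1.5 * d_closed, tolerance = 1e-12)
  cm <- classifyContacts(open_at, closed, "ca_cutoff", cutoff = 0.8,
                         min_seq_sep = 4)
  expect_equal(cm$class[cm$res_i == 1 & cm$res_j == 5], "discarded")

  # present in both -> common regardless of ratio
  open_near <- mkCa(0.75)
  cm <- classifyContacts(open_near, closed, "ca_cutoff", cutoff = 0.8,
                         min_seq_sep = 4)
  expect_equal(cm$class[cm$res_i == 1 & cm$res_j == 5], "common")
})

test_that("raising the ratio never increases state-specific counts", {
  toy <- toyFixture()
  prev <- Inf
  for (ratio in c(1.2, 1.5, 1.8, 2.5)) {
    cm <- classifyContacts(toy$open, toy$closed, "ca_cutoff", cutoff = 0.8,
                           min_seq_sep = 4, ratio = ratio)
    cc <- classCounts(cm)
    n_specific <- cc[["open_specific"]] + cc[["closed_specific"]]
    expect_lte(n_specific, prev)
    prev <- n_specific
  }
})

test_that("class counts add up and tail involvement is tracked", {
  toy <- toyFixture()
  cc <- classCounts(toy$contacts)
  expect_equal(sum(cc[c("common", "open_specific", "closed_specific",
                        "discarded")]),
               nrow(toy$contacts))
  # all open-specific contacts of the toy involve the docked tail
  expect_gt(cc[["open_specific_cth"]], 0)
  empty <- toy$contacts[0, ]
  expect_equal(unname(classCounts(empty)), rep(0L, 5))
})

test_that("contact maps round-trip through TSV losslessly", {
  toy <- toyFixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeContactMap(toy$contacts, path)
  back <- readContactMap(path)
  expect_equal(back$res_i, toy$contacts$res_i)
  expect_equal(back$class, toy$contacts$class)
  expect_equal(back$involves_cth, toy$contacts$involves_cth)
  expect_lt(max(abs(back$d_open - toy$contacts$d_open)), 1e-6)
  expect_lt(max(abs(back$d_closed - toy$contacts$d_closed)), 1e-6)
  p_in <- attr(toy$contacts, "params"); p_out <- attr(back, "params")
  expect_equal(p_out$cutoff, p_in$cutoff)
  expect_equal(p_out$ratio, p_in$ratio)
  expect_equal(p_out$cth_range, p_in$cth_range)

  # duplicate pairs are rejected
  lines <- readLines(path)
  dup <- c(lines, tail(lines, 1))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(dup, path2)
  expect_error(readContactMap(path2), "duplicate pair")
})
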
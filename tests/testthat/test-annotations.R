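test_that("interval LAB files parse into validated hierarchies", {
  p1 <- tempfile(fileext = ".lab")
  writeLines("0.0 180.0 A", p1)
  h <- read_annotation(p1)
  expect_equal(hier_depth(h), 1)
  expect_equal(nrow(h), 1)
  expect_equal(hier_duration(h), 180)
  expect_equal(h$label, "A")

  coarse <- write_lab(data.frame(start = c(0, 60, 120), end = c(60, 120, 180),
                                 label = c("A", "B", "A")))
  fine <- write_lab(data.frame(start = c(0, 30, 60, 90, 120, 150),
                               end = c(30, 60, 90, 120, 150, 180),
                               label = c("a", "b", "c", "c", "a", "b")))
  h2 <- read_annotation(c(coarse, fine))
  expect_equal(hier_depth(h2), 2)
  for (k in 1:2) {
    lev <- h2[h2$level == k, ]
    expect_equal(sum(lev$end - lev$start), 180)
  }
})

test_that("level selection drops unwanted levels (e.g. a function level)", {
  mk <- function(lab) write_lab(data.frame(start = 0, end = 100, label = lab))
  paths <- c(coarse = mk("A"), fine = mk("a"), `function` = mk("verse"))
  h <- read_annotation(paths, levels = c("coarse", "fine"))
  expect_equal(hier_depth(h), 2)
  expect_false("verse" %in% h$label)
  expect_equal(h$level_name, c("coarse", "fine"))
  expect_error(read_annotation(paths, levels = "bridge"), "unknown level")
})

test_that("SALAMI boundary files parse with last line as track end", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("0.0\tA", "12.5\tB", "30.0\tEnd"), p)
  h <- read_annotation(p, format = "salami_boundary")
  expect_equal(nrow(h), 2)
  expect_equal(h$start, c(0, 12.5))
  expect_equal(h$end, c(12.5, 30))
  expect_equal(h$label, c("A", "B"))
})

test_that("malformed and invalid files produce located errors", {
  p <- tempfile(fileext = ".lab")
  writeLines(c("0 10 A", "10 twenty B"), p)
  expect_error(read_annotation(p), ":2:")
  p2 <- tempfile(fileext = ".lab")
  writeLines(c("0 10 A", "10"), p2)
  expect_error(read_annotation(p2), ":2:")
  p3 <- tempfile(fileext = ".lab")
  writeLines(character(0), p3)
  expect_error(read_annotation(p3), "empty annotation level")
  expect_error(read_annotation(tempfile()), "not found")
})

test_that("small boundary jitter is snapped to the midpoint, large gaps error", {
  h <- as_hierarchy(data.frame(start = c(0, 10.008), end = c(10, 20),
                               label = c("A", "B")))
  expect_equal(h$end[1], 10.004)
  expect_equal(h$start[2], 10.004)
  expect_error(
    as_hierarchy(data.frame(start = c(0, 10.5), end = c(10, 20),
                            label = c("A", "B"))),
    "gap"
  )
  expect_error(
    as_hierarchy(data.frame(start = c(0, 9.5), end = c(10, 20),
                            label = c("A", "B"))),
    "overlap"
  )
  expect_error(as_hierarchy(data.frame(start = 0, end = 10, label = "  ")),
               "empty segment label")
  expect_error(as_hierarchy(data.frame(start = 5, end = 3, label = "A")),
               "end <= start")
})

test_that("write/read round-trip preserves boundaries to 1e-6 and labels exactly", {
  set.seed(42)
  for (i in 1:10) {
    h <- random_hierarchy(duration = runif(1, 30, 200), depth = sample(1:3, 1))
    paths <- replicate(hier_depth(h), tempfile(fileext = ".lab"))
    write_annotation(h, paths)
    h2 <- read_annotation(paths)
    expect_lt(max(abs(h2$start - h$start)), 1e-6)
    expect_lt(max(abs(h2$end - h$end)), 1e-6)
    expect_identical(h2$label, h$label)
  }
})

test_that("frame sampling follows the half-open convention", {
  h1 <- as_hierarchy(data.frame(start = 0, end = 1, label = "A"))
  g1 <- sample_labels(h1, 10)
  expect_equal(ncol(g1), 10)
  expect_true(all(unclass(g1) == unclass(g1)[1, 1]))

  h2 <- as_hierarchy(data.frame(start = c(0, 0.25), end = c(0.25, 0.6),
                                label = c("A", "B")))
  g2 <- sample_labels(h2, 10)
  expect_equal(ncol(g2), 6)
  expect_equal(as.vector(unclass(g2)), c(1, 1, 1, 2, 2, 2))

  # n_frames contract on arbitrary hierarchies
  for (seed in 1:5) {
    h <- random_hierarchy(duration = runif(1, 10, 60), depth = 2, seed = seed)
    g <- sample_labels(h, 10)
    expect_equal(ncol(g), ceiling(hier_duration(h) * 10 - 1e-9))
    expect_equal(nrow(g), 2)
  }
})

test_that("boundaries are recoverable from sampled labels to within one frame", {
  for (seed in 1:10) {
    fr <- 10
    h <- random_hierarchy(duration = 60, depth = 2, seed = seed)
    g <- sample_labels(h, fr)
    for (k in 1:2) {
      seq_k <- unclass(g)[k, ]
      change <- which(diff(seq_k) != 0) / fr  # time of frame after the change
      seg <- h[h$level == k, ]
      interior <- seg$end[-nrow(seg)]
      # every true label-change boundary has a recovered change-point nearby
      lab_change <- interior[seg$label[-nrow(seg)] != seg$label[-1]]
      for (b in lab_change) {
        expect_lt(min(abs(change - b)), 1 / fr + 1e-9)
      }
    }
  }
})

test_that("label recoding leaves the grid's equality structure unchanged", {
  set.seed(7)
  for (i in 1:20) {
    labs <- matrix(sample(LETTERS[1:4], 30, replace = TRUE), nrow = 2)
    g1 <- frame_grid(labs)
    perm <- setNames(sample(letters[1:4]), LETTERS[1:4])
    g2 <- frame_grid(matrix(perm[labs], nrow = 2))
    expect_identical(unclass(g1), unclass(g2))
  }
})

test_that("align_pair truncates to the shorter annotation", {
  h1 <- random_hierarchy(duration = 180, depth = 2, seed = 1)
  h2 <- random_hierarchy(duration = 180, depth = 2, seed = 2)
  g <- align_pair(h1, h2, 10)
  expect_equal(ncol(g$ref), ncol(g$est))

  h3 <- random_hierarchy(duration = 180.4, depth = 2, seed = 3)
  expect_no_warning(g2 <- align_pair(h1, h3, 10, tolerance = 1))
  expect_equal(ncol(g2$ref), 1800)

  h4 <- random_hierarchy(duration = 200, depth = 2, seed = 4)
  expect_warning(g3 <- align_pair(h1, h4, 10, tolerance = 1), "truncating")
  expect_equal(ncol(g3$ref), 1800)
  expect_equal(ncol(g3$est), 1800)

  h5 <- random_hierarchy(duration = 500, depth = 2, seed = 5)
  expect_error(align_pair(h1, h5, 10), "differ by more than")
})
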
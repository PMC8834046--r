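# Segment I/O and the fraction of genome altered.

test_that("SEG files round-trip through write_seg and read_seg", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c(
    "sample_id\tchrom\tloc_start\tloc_end\tseg_mean",
    "s1\t1\t1\t1000\t0.5",
    "s1\t2\t501\t2000\t-0.1"
  ), path)
  profiles <- read_seg(path)
  expect_length(profiles, 1)
  expect_equal(nrow(profiles$s1$segments), 2)
  # 1-based inclusive -> 0-based half-open
  expect_equal(profiles$s1$segments$start, c(0, 500))
  expect_equal(profiles$s1$segments$end, c(1000, 2000))

  set.seed(11)
  rnd <- list(a = rnd_profile("a", 100), b = rnd_profile("b", 40))
  out <- withr::local_tempfile(fileext = ".seg")
  write_seg(rnd, out)
  back <- read_seg(out)
  expect_equal(names(back), c("a", "b"))
  for (nm in names(rnd)) {
    expect_equal(back[[nm]]$segments$chrom, rnd[[nm]]$segments$chrom)
    expect_equal(back[[nm]]$segments$start, rnd[[nm]]$segments$start)
    expect_equal(back[[nm]]$segments$end, rnd[[nm]]$segments$end)
    expect_equal(back[[nm]]$segments$log2_ratio, rnd[[nm]]$segments$log2_ratio,
      tolerance = 1e-12
    )
  }

  empty <- withr::local_tempfile(fileext = ".seg")
  write_seg(list(), empty)
  expect_length(readLines(empty), 1) # header only
  expect_length(read_seg(empty), 0)
})

test_that("malformed SEG rows raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c(
    "sample_id\tchrom\tloc_start\tloc_end\tseg_mean",
    "s1\t1\t1\t1000\t0.5",
    "s1\t1\t5000\t2000\t0.1"
  ), path)
  expect_error(read_seg(path), "line 3")

  writeLines(c(
    "sample_id\tchrom\tloc_start\tloc_end\tseg_mean",
    "s1\t1\toops\t1000\t0.5"
  ), path)
  expect_error(read_seg(path), "line 2")
})

test_that("non-finite segment means are dropped with a count", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c(
    "sample_id\tchrom\tloc_start\tloc_end\tseg_mean",
    "s1\t1\t1\t1000\t0.5",
    "s1\t2\t1\t1000\tNA"
  ), path)
  expect_message(profiles <- read_seg(path), "dropped 1")
  expect_equal(nrow(profiles$s1$segments), 1)
})

test_that("overlapping segments within a sample are rejected", {
  expect_error(
    segment_profile("s1", data.frame(
      chrom = c("1", "1"), start = c(0, 500), end = c(1000, 1500),
      log2_ratio = c(0.1, 0.2)
    )),
    "overlapping"
  )
})

test_that("compute_fga matches hand-computed alteration fractions", {
  p0 <- segment_profile("s", data.frame(
    chrom = "1", start = 0, end = 1000, log2_ratio = 0
  ))
  expect_equal(compute_fga(p0)$fga, 0)

  p1 <- segment_profile("s", data.frame(
    chrom = "1", start = 0, end = 1000, log2_ratio = 0.5
  ))
  expect_equal(compute_fga(p1)$fga, 1)

  # deletions count through the magnitude: 600 + 1000 altered of 2000
  p2 <- segment_profile("s", data.frame(
    chrom = c("1", "1", "2"), start = c(0, 600, 0),
    end = c(600, 1000, 1000), log2_ratio = c(0.3, 0.1, -0.25)
  ))
  v <- compute_fga(p2)
  expect_equal(v$fga, 1600 / 2000)
  expect_equal(v$altered_length, 1600)
  expect_equal(v$total_length, 2000)

  empty <- segment_profile("s", data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    log2_ratio = numeric(0)
  ))
  expect_error(compute_fga(empty), "empty")
})

test_that("linear copy-number dialect thresholds |value - 1|", {
  p <- segment_profile("s", data.frame(
    chrom = c("1", "1", "1"), start = c(0, 100, 300),
    end = c(100, 300, 600), log2_ratio = c(1.0, 1.25, 0.75)
  ))
  v <- compute_fga(p, linear = TRUE)
  expect_equal(v$fga, 500 / 600) # 1.25 and 0.75 deviate by 0.25 from 1
})

test_that("fga is a proper fraction, monotone in threshold, and invariant to rescaling and splitting", {
  set.seed(21)
  for (i in 1:40) {
    p <- rnd_profile(n_seg = sample(5:40, 1))
    f <- compute_fga(p)$fga
    expect_gte(f, 0)
    expect_lte(f, 1)
    expect_equal(f, brute_fga(p))

    # non-increasing in the alteration threshold
    fs <- vapply(
      c(0.05, 0.2, 0.4, 0.8),
      function(t) compute_fga(p, t)$fga, numeric(1)
    )
    expect_true(all(diff(fs) <= 0))

    # coordinate rescaling leaves the fraction unchanged
    scaled <- segment_profile(p$sample_id, transform(
      p$segments,
      start = start * 3, end = end * 3
    ))
    expect_equal(compute_fga(scaled)$fga, f)

    # splitting any segment into abutting halves changes nothing
    seg <- p$segments
    halves <- do.call(rbind, lapply(seq_len(nrow(seg)), function(j) {
      mid <- floor((seg$start[j] + seg$end[j]) / 2)
      if (mid > seg$start[j] && mid < seg$end[j]) {
        data.frame(
          chrom = seg$chrom[j], start = c(seg$start[j], mid),
          end = c(mid, seg$end[j]), log2_ratio = seg$log2_ratio[j]
        )
      } else {
        seg[j, c("chrom", "start", "end", "log2_ratio")]
      }
    }))
    expect_equal(compute_fga(segment_profile("x", halves))$fga, f)
  }
})

test_that("fga_table collects one row per profile", {
  set.seed(3)
  profs <- list(a = rnd_profile("a"), b = rnd_profile("b"))
  tab <- fga_table(profs)
  expect_equal(tab$sample_id, c("a", "b"))
  expect_equal(tab$fga, c(brute_fga(profs$a), brute_fga(profs$b)))
})
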
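test_that("valid_kmer_starts drops exactly the centre-covering starts", {
  s <- valid_kmer_starts(41, 4, 21)
  expect_length(s, 34L)
  expect_equal(s, c(1:17, 22:38))
  # brute-force filter over all 38 starts
  brute <- Filter(function(x) !(x <= 21 && 21 <= x + 3), 1:38)
  expect_equal(s, brute)
  expect_setequal(setdiff(1:38, s), 18:21)

  expect_equal(valid_kmer_starts(7, 2, 4), c(1, 2, 5, 6))
  expect_error(valid_kmer_starts(41, 4, 50), "center")
  expect_error(valid_kmer_starts(41, 50, 21), "k must")
})

test_that("descriptor_for recovers slot, start, dim and covered positions", {
  d1 <- descriptor_for(1)
  expect_equal(d1$slot, 1L); expect_equal(d1$start, 1L)
  expect_equal(d1$emb_dim, 1L)
  expect_equal(d1$covered_positions[[1]], 1:4)

  dlast <- descriptor_for(1020)
  expect_equal(dlast$slot, 34L); expect_equal(dlast$start, 38L)
  expect_equal(dlast$emb_dim, 30L)
  expect_equal(dlast$covered_positions[[1]], 38:41)

  dmid <- descriptor_for(511)
  expect_equal(dmid$slot, 18L); expect_equal(dmid$start, 22L)
  expect_equal(dmid$emb_dim, 1L)
  expect_equal(dmid$covered_positions[[1]], 22:25)

  expect_error(descriptor_for(1021), "argument error")
  expect_error(descriptor_for(0), "argument error")
})

test_that("no descriptor covers the centre and column count is dim x slots", {
  for (geom in list(c(41, 4, 21), c(41, 3, 21), c(21, 4, 11), c(7, 2, 4))) {
    starts <- valid_kmer_starts(geom[1], geom[2], geom[3])
    desc <- feature_descriptors(dim = 5, starts = starts, k = geom[2])
    expect_equal(nrow(desc), 5L * length(starts))
    expect_false(any(vapply(desc$covered_positions,
                            function(p) geom[3] %in% p, logical(1))))
  }
})

test_that("encode_windows assembles slot-major embedding blocks", {
  # hand-assembled toy: window AACAGGU (len 7), k=2, dim=2, centre 4
  tab <- toy_table_2mer()   # AA=(1,2) AC=(3,4) CA=(5,6) GG=(7,8) GU=(9,10)
  rec <- site_records("w1", "AACAGGU", "positive", flank = 3,
                      center_check = FALSE)
  fm <- encode_windows(rec, tab, center = 4)
  expect_equal(ncol(fm$values), 8L)  # 4 valid slots x 2 dims
  expect_equal(unname(fm$values[1, ]), c(1, 2, 3, 4, 7, 8, 9, 10))
  expect_equal(colnames(fm$values)[1:2], c("s1d1", "s1d2"))
})

test_that("41-nt windows with a 4-mer/30-dim table give the 1020-column matrix", {
  cfg <- synth_config(n_pos = 4, n_neg = 4, seed = 2)
  tab <- generate_embeddings(4, 30, "gaussian", seed = 2)
  fm <- encode_windows(generate_dataset(cfg), tab)
  expect_equal(dim(fm$values), c(8L, 1020L))
  expect_equal(nrow(fm$descriptors), 1020L)
  expect_equal(fm$starts, c(1:17, 22:38))
})

test_that("an all-zero table propagates to an all-zero matrix", {
  kmers <- sort(do.call(paste0, rev(expand.grid(rep(list(c("A","C","G","U")), 2),
                                                stringsAsFactors = FALSE))))
  tab <- embedding_table(matrix(0, 16, 3, dimnames = list(kmers)))
  rec <- site_records(c("a", "b"), c("AACAGGU", "UUUCAAA"), c("positive", "negative"),
                      flank = 3, center_check = FALSE)
  fm <- encode_windows(rec, tab, center = 4)
  expect_true(all(fm$values == 0))
})

test_that("encoding under a one-hot table separates windows differing outside the centre k-mers", {
  tab <- one_hot_table(k = 2)
  recs <- site_records(c("a", "b", "c"),
                       c("AACAGGU", "AACAGGA", "AACAGGU"),
                       c("positive", "negative", "positive"), flank = 3,
                       center_check = FALSE)
  fm <- encode_windows(recs, tab, center = 4)
  expect_false(isTRUE(all.equal(fm$values[1, ], fm$values[2, ])))
  expect_equal(unname(fm$values[1, ]), unname(fm$values[3, ]))
})

test_that("lookup failures name the record and slot; zero policy fills zeros", {
  tab <- toy_table_2mer()  # lacks e.g. UU
  rec <- site_records("w2", "UUCAGGU", "positive", flank = 3, center_check = FALSE)
  expect_error(encode_windows(rec, tab, center = 4), "w2.*slot 1|slot 1.*w2")
  fm <- encode_windows(rec, tab, center = 4, missing = "zero")
  expect_equal(unname(fm$values[1, 1:2]), c(0, 0))
})

test_that("inconsistent window lengths are rejected", {
  rec <- data.frame(id = c("a", "b"), window = c("AACAGGU", "AACAGGUU"),
                    label = c("positive", "negative"))
  expect_error(encode_windows(rec, toy_table_2mer(), center = 4),
               "inconsistent")
})

test_that("feature-matrix TSV export writes values and descriptor sidecar", {
  tab <- toy_table_2mer()
  rec <- site_records(c("a", "b"), c("AACAGGU", "CAAAGGU"),
                      c("positive", "negative"), flank = 3, center_check = FALSE)
  fm <- encode_windows(rec, tab, center = 4)
  prefix <- tempfile()
  paths <- write_feature_matrix(fm, prefix)
  values <- read.delim(paths[1], check.names = FALSE)
  expect_equal(nrow(values), 2L)
  expect_equal(names(values)[1:2], c("id", "label"))
  desc <- read.delim(paths[2])
  expect_equal(nrow(desc), 8L)
  expect_equal(desc$covered_positions[1], "1,2")
})
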
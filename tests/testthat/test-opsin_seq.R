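# Sequence ingestion, bovine numbering, site extraction, identity screening.

test_that("FASTA reading parses records, infers classes, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rh2_1 cloned", "MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSML"),
             f)
  recs <- read_opsin_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "rh2_1")
  expect_equal(recs[[1]]$opsin_class, "rh2")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_opsin_fasta(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">weird", "MNGT3EG"), bad)
  expect_error(read_opsin_fasta(bad), "weird")
})

test_that("a generated 11-gene repertoire round-trips through FASTA", {
  classes <- c("rh1", "sws1", "sws2", rep("rh2", 4), rep("lws", 4))
  seqs <- lapply(seq_along(classes), function(i) {
    s <- make_sequence(sequence_recipe(classes[i], seed = i))
    s$id <- paste0(classes[i], "_", i)
    s
  })
  f <- withr::local_tempfile(fileext = ".fasta")
  write_opsin_fasta(seqs, f)
  back <- read_opsin_fasta(f)
  expect_length(back, 11)
  expect_equal(vapply(back, function(s) s$opsin_class, character(1)),
               classes)
  expect_equal(back[[1]]$protein, seqs[[1]]$protein)
})

test_that("CDS and protein must be mutually consistent", {
  expect_error(opsin_sequence("x", cds = "ATGGCT", protein = "MS"),
               "does not match")
  s <- opsin_sequence("ok", cds = "ATGGCTTAA")
  expect_equal(s$protein, "MA")
})

test_that("bovine self-alignment gives the identity numbering map", {
  ref <- bovine_rhodopsin()
  expect_equal(nchar(ref$protein), 348)
  # guard on the packaged reference: canonical rod-opsin residues
  key <- c("83" = "D", "113" = "E", "122" = "E", "181" = "E", "261" = "F",
           "265" = "W", "292" = "A", "296" = "K")
  for (s in names(key)) {
    expect_equal(substr(ref$protein, as.integer(s), as.integer(s)),
                 unname(key[s]))
  }
  m <- map_to_bovine_numbering(ref)
  expect_equal(m$query_pos, 1:348)
  expect_equal(m$bovine_pos, 1:348)
  expect_false(attr(m, "unreliable"))
})

test_that("an N-terminal insertion offsets the numbering by one", {
  ref <- bovine_rhodopsin()
  # a G prepended to the M-initiated reference gaps unambiguously
  q <- opsin_sequence("plus1", protein = paste0("G", ref$protein))
  m <- map_to_bovine_numbering(q)
  ok <- !is.na(m$query_pos) & !is.na(m$bovine_pos)
  expect_equal(m$query_pos[ok], m$bovine_pos[ok] + 1L)
})

test_that("numbering positions are strictly increasing over non-gap pairs", {
  s <- make_sequence(sequence_recipe("rh2", site_residues = c("122" = "Q"),
                                     seed = 9))
  m <- map_to_bovine_numbering(s)
  expect_true(all(diff(m$query_pos[!is.na(m$query_pos)]) == 1L))
  expect_true(all(diff(m$bovine_pos[!is.na(m$bovine_pos)]) == 1L))
  expect_true(all(m$bovine_pos[!is.na(m$bovine_pos)] %in% 1:348))
})

test_that("planted tuning-site residues are recovered for every class", {
  plants <- list(
    lws = c("164" = "A", "181" = "Y", "261" = "F", "269" = "T",
            "292" = "S"),
    sws1 = c("86" = "F"),
    rh2 = c("122" = "Q"))
  for (cl in names(plants)) {
    s <- make_sequence(sequence_recipe(cl, site_residues = plants[[cl]],
                                       seed = 3))
    prof <- extract_tuning_sites(s, map_to_bovine_numbering(s), cl)
    expect_equal(prof[names(plants[[cl]])], plants[[cl]],
                 ignore_attr = TRUE)
  }
})

test_that("a deletion spanning a tuning site yields '-'", {
  # remove codons 180-182 so bovine site 181 is unalignable
  s <- make_sequence(sequence_recipe("lws",
                                     lesions = list(lesion("deletion",
                                                           538, 9))))
  prof <- extract_tuning_sites(s, map_to_bovine_numbering(s), "lws")
  expect_equal(prof[["181"]], "-")
  expect_true(all(prof[c("164", "261", "269", "292")] != "-"))
})

test_that("extract_tuning_sites rejects unknown classes", {
  ref <- bovine_rhodopsin()
  m <- map_to_bovine_numbering(ref)
  expect_error(extract_tuning_sites(ref, m, "opn4"), "valid classes")
})

test_that("percent identity is exact on contrived pairs and symmetric", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(percent_identity("AAAA", "AATT"), 50)
  set.seed(11)
  a <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 280, replace = TRUE),
             collapse = "")
  expect_equal(percent_identity(a, b), percent_identity(b, a))
})

test_that("identity of a mutated copy matches the substitution rate", {
  set.seed(7)
  n <- 1000
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n, replace = TRUE)
  b <- a
  hit <- runif(n) < 0.13
  b[hit] <- vapply(a[hit], function(x) sample(setdiff(bases, x), 1),
                   character(1))
  pid <- percent_identity(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_gt(pid, 84)
  expect_lt(pid, 90)
})

test_that("cross-hybridization bands follow the 65/90 thresholds", {
  expect_equal(cross_hybridization_flag(92), "hybridizes")
  expect_equal(cross_hybridization_flag(90), "hybridizes")
  expect_equal(cross_hybridization_flag(87), "uncertain")
  expect_equal(cross_hybridization_flag(65), "no_cross")
  expect_equal(cross_hybridization_flag(60), "no_cross")
})

test_that("codon-aware identity matrix flags same-class paralogue risk", {
  a <- make_sequence(sequence_recipe("rh2", seed = 1))
  b <- make_sequence(sequence_recipe("rh2", site_residues = c("122" = "Q"),
                                     seed = 2))
  b$id <- "rh2_b"
  m <- identity_matrix(list(a, b))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(diag(m)), c(100, 100))
  # one planted codon changed out of 349
  expect_gt(m[1, 2], 99)
  expect_equal(cross_hybridization_flag(m[1, 2]), "hybridizes")
})

test_that("site profile TSV export has the documented columns", {
  s <- make_sequence(sequence_recipe("sws1", site_residues = c("86" = "F")))
  prof <- extract_tuning_sites(s, map_to_bovine_numbering(s), "sws1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_profile_tsv(prof, f)
  # one-letter residue codes include T and F; keep them out of logicals
  df <- read.delim(f, colClasses = c(residue = "character"))
  expect_named(df, c("pigment_id", "class", "site", "residue"))
  expect_equal(df$residue[df$site == 86], "F")
})
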
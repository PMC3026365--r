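test_that("FASTA parsing maps headers and concatenates sequence lines", {
  r <- read_fasta(text = ">q1 desc\nACGT\n")
  expect_equal(r$id, "q1")
  expect_equal(r$description, "desc")
  expect_equal(r$residues, "ACGT")

  expect_equal(nrow(read_fasta(text = "")), 0L)

  r2 <- read_fasta(text = ">a\nAC\nGT\n>b\nTTTT\n")
  expect_equal(r2$residues, c("ACGT", "TTTT"))
  expect_equal(r2$id, c("a", "b"))

  # lowercase input is uppercased; U survives import unchanged
  r3 <- read_fasta(text = ">u\nacgu\n")
  expect_equal(r3$residues, "ACGU")

  # header with no description
  expect_equal(read_fasta(text = ">solo\nAAAA\n")$description, "")
})

test_that("FASTA parse errors name the offending line", {
  expect_error(read_fasta(text = "ACGT\n>q1\nACGT\n"),
               "line 1.*before any header")
  expect_error(read_fasta(text = ">q1\n>q2\nACGT\n"), "line 1.*empty record")
  expect_error(read_fasta(text = ">q1 ok\nAC\n>q2\n"), "line 3.*empty record")
})

test_that("FASTA write wraps at 60 columns and round-trips exactly", {
  rec <- read_fasta(text = ">q1 d\nACGT\n")
  expect_equal(as.character(write_fasta(rec)), ">q1 d\nACGT\n")
  expect_equal(as.character(write_fasta(rec[0, ])), "")

  long <- data.frame(id = "L", accession = NA_character_, description = "",
                     residues = strrep("ACGTA", 26), # 130 residues
                     source_format = "fasta", stringsAsFactors = FALSE)
  txt <- as.character(write_fasta(long))
  body <- strsplit(txt, "\n")[[1]][-1]
  expect_equal(nchar(body), c(60L, 60L, 10L))

  set.seed(42)
  recs <- data.frame(
    id = sprintf("seq%02d_%s", 1:20, replicate(20, rand_seq(4))),
    accession = NA_character_,
    description = c("", replicate(19, paste(sample(letters, 5), collapse = " "))),
    residues = replicate(20, rand_seq(sample(1:200, 1))),
    source_format = "fasta", stringsAsFactors = FALSE)
  back <- read_fasta(text = as.character(write_fasta(recs)))
  expect_equal(back$id, recs$id)
  expect_equal(back$description, recs$description)
  expect_equal(back$residues, recs$residues)
})

test_that("written FASTA agrees with an independent reader", {
  recs <- data.frame(id = c("a1", "b2"), accession = NA_character_,
                     description = c("first", ""),
                     residues = c(strrep("ACGT", 40), "TTGGCCAA"),
                     source_format = "fasta", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  alt <- seqinr::read.fasta(f, as.string = TRUE, forceDNAtolower = FALSE)
  expect_equal(names(alt), recs$id)
  expect_equal(toupper(unname(vapply(alt, as.character, character(1)))),
               recs$residues)
})

test_that("GenBank entries yield id, accession, description and residues", {
  gb <- paste(
    "LOCUS       x1            8 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  a test organism 16S ribosomal RNA gene,",
    "            partial sequence.",
    "ACCESSION   AB000001",
    "ORIGIN",
    "        1 acgtacgt",
    "//", sep = "\n")
  r <- read_genbank(text = gb)
  expect_equal(r$id, "x1")
  expect_equal(r$accession, "AB000001")
  expect_equal(r$residues, "ACGTACGT")
  expect_match(r$description, "partial sequence\\.$")

  two <- paste(gb, sub("x1", "x2", gb), sep = "\n")
  expect_equal(read_genbank(text = two)$id, c("x1", "x2"))

  no_origin <- paste("LOCUS       y1    4 bp", "DEFINITION  d.", "//", sep = "\n")
  expect_error(read_genbank(text = no_origin), "y1.*missing ORIGIN")
  expect_error(read_genbank(text = "DEFINITION  d.\nORIGIN\n1 acgt\n//"),
               "missing LOCUS")
  expect_equal(nrow(read_genbank(text = "")), 0L)
})

test_that("raw import takes one sequence per non-empty line", {
  r <- read_raw(text = "acgt\n\nTTAA\n")
  expect_equal(r$id, c("raw_1", "raw_2"))
  expect_equal(r$residues, c("ACGT", "TTAA"))
  expect_equal(nrow(read_raw(text = "")), 0L)
  expect_equal(read_raw(text = "AC GT\n")$residues, "ACGT")
  expect_error(read_raw(text = "ACGT\nAXZT\n"), "line 2.*non-IUPAC")
})

test_that("collections enforce unique non-empty records", {
  recs <- read_fasta(text = ">a\nAC\n>b\nGT\n>c\nTT\n")
  coll <- create_collection("survey", recs)
  expect_s3_class(coll, "collection")
  expect_equal(nrow(coll$records), 3L)
  expect_equal(coll$import_params$source_format, "fasta")
  expect_equal(coll$import_params$record_count, 3L)

  dup <- rbind(recs[1, ], recs[1, ])
  expect_error(create_collection("bad", dup), "duplicate record id.*a")
  expect_error(create_collection("empty", recs[0, ]), "at least one")
})
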
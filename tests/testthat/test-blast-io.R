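test_that("tabular rows map to hit evidence fields", {
  res <- parse_blast_tabular(
    text = "q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t181\n")
  expect_length(res, 1L)
  h <- res[[1]]$hits
  expect_equal(res[[1]]$query_id, "q1")
  expect_equal(h$subject_id, "s1")
  expect_equal(h$evalue, 1e-50)
  expect_equal(h$bit_score, 181)
  expect_equal(h$percent_identity, 98.5)
  expect_equal(h$rank, 1L)
  expect_equal(h$strand, "plus")

  # duplicated pair keeps the higher-scoring row
  two <- paste0("q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t181\n",
                "q1\ts1\t97.0\t100\t3\t0\t1\t100\t1\t100\t1e-45\t150\n")
  h2 <- parse_blast_tabular(text = two)[[1]]$hits
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$bit_score, 181)

  expect_equal(parse_blast_tabular(text = "# comment only\n"), list())
  # minus strand encoded by reversed subject coordinates
  ms <- parse_blast_tabular(
    text = "q1\ts1\t90\t50\t5\t0\t1\t50\t80\t31\t1e-10\t70\n")[[1]]$hits
  expect_equal(ms$strand, "minus")
  expect_gt(ms$s_start, ms$s_end)
})

test_that("tabular parse errors carry line numbers", {
  expect_error(parse_blast_tabular(text = "q1\ts1\t98.5\n"),
               "line 1.*3 field")
  bad2 <- paste0("q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t181\n",
                 "q1\ts2\tnope\t100\t1\t0\t1\t100\t1\t100\t1e-50\t181\n")
  expect_error(parse_blast_tabular(text = bad2), "line 2.*pident.*nope")
})

test_that("XML iterations produce ranked hits with best-HSP evidence", {
  xml <- blast_xml_text(list(
    list(query = "q1", hits = list(
      list(subject = "s1", hsps = list(
        list(bit = 95, evalue = "1e-40", ident = 95, alen = 100, sseq = "ACGT"))),
      list(subject = "s2", hsps = list(
        list(bit = 80, evalue = "1e-30", ident = 90, alen = 100)))))))
  res <- parse_blast_xml(text = xml)
  expect_length(res, 1L)
  h <- res[[1]]$hits
  expect_equal(h$subject_id, c("s1", "s2"))
  expect_equal(h$rank, c(1L, 2L))
  expect_equal(h$percent_identity, c(95, 90))
  expect_equal(h$subject_aligned_segment[1], "ACGT")

  # two HSPs: the better one (bit 95) wins
  xml2h <- blast_xml_text(list(
    list(query = "q1", hits = list(
      list(subject = "s1", hsps = list(
        list(bit = 80, evalue = "1e-30", ident = 80, alen = 100),
        list(bit = 95, evalue = "1e-40", ident = 95, alen = 100)))))))
  h2 <- parse_blast_xml(text = xml2h)[[1]]$hits
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$bit_score, 95)
  expect_equal(h2$percent_identity, 95)

  # empty iteration is a valid result with no hits
  empty <- blast_xml_text(list(list(query = "q9", hits = list())))
  res3 <- parse_blast_xml(text = empty)
  expect_equal(res3[[1]]$query_id, "q9")
  expect_equal(nrow(res3[[1]]$hits), 0L)

  expect_error(parse_blast_xml(text = "<notblast/>"), "root element")
  expect_error(parse_blast_xml(text = "<BlastOutput><unclosed>"),
               "parse error")
})

test_that("XML minus-strand hits are detected from reversed coordinates", {
  xml <- blast_xml_text(list(
    list(query = "q1", hits = list(
      list(subject = "s1", hsps = list(
        list(bit = 90, evalue = "1e-33", ident = 88, alen = 90,
             sfrom = 120, sto = 31, sseq = "AACG")))))))
  h <- parse_blast_xml(text = xml)[[1]]$hits
  expect_equal(h$strand, "minus")
})

test_that("evidence deduplication follows the fixed tie-break chain", {
  base <- parse_blast_tabular(
    text = "q\ts\t90\t100\t1\t0\t1\t100\t1\t100\t1e-30\t100\n")[[1]]$hits
  mk <- function(bit, evalue, alen) {
    r <- base; r$bit_score <- bit; r$evalue <- evalue; r$align_length <- alen; r
  }
  # higher bit wins
  expect_equal(dedupe_evidence(rbind(mk(100, 1e-30, 100),
                                     mk(90, 1e-40, 100)))$bit_score, 100)
  # bit tie -> lower evalue
  expect_equal(dedupe_evidence(rbind(mk(100, 1e-30, 100),
                                     mk(100, 1e-40, 100)))$evalue, 1e-40)
  # bit+evalue tie -> larger align_length
  expect_equal(dedupe_evidence(rbind(mk(100, 1e-30, 80),
                                     mk(100, 1e-30, 120)))$align_length, 120L)
  # full tie -> first occurrence
  a <- mk(100, 1e-30, 100); a$s_start <- 7L
  expect_equal(dedupe_evidence(rbind(a, mk(100, 1e-30, 100)))$s_start, 7L)
  # identity case
  expect_equal(dedupe_evidence(mk(100, 1e-30, 100)), mk(100, 1e-30, 100))
})

test_that("parsed results have contiguous ranks and are dedupe-stable", {
  b <- generate_fixture(fixture_spec(8, 30, density = 0.3, seed = 5))
  for (res in list(parse_blast_tabular(text = b$blast_tab),
                   parse_blast_xml(text = b$blast_xml))) {
    for (qr in res) {
      expect_equal(qr$hits$rank, seq_len(nrow(qr$hits)))
      expect_false(anyDuplicated(qr$hits$subject_id) > 0)
      # re-feeding parsed rows through dedupe is the identity
      for (k in seq_len(nrow(qr$hits))) {
        expect_equal(dedupe_evidence(qr$hits[k, , drop = FALSE]),
                     qr$hits[k, , drop = FALSE])
      }
    }
  }
})
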
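test_that("in-silico bisulfite conversion applies the per-base rules", {
  expect_equal(bisulfite_convert("ACAT"), "ATAT")
  expect_equal(bisulfite_convert("ACGT", "cpg_methylated"), "ACGT")
  expect_equal(bisulfite_convert("ACGT"), "ATGT")
  expect_equal(bisulfite_convert("acgt", "none"), "ACGT")
  # bottom strand: reverse complement, then convert, reported 5'->3'
  expect_equal(bisulfite_convert("ACGT", strand = "bottom"),
               bisulfite_convert(revcomp_chr("ACGT")))
  expect_error(bisulfite_convert("ACXT"), "non-DNA")
})

test_that("conversion of random kilobase sequences matches the per-base
           oracle and is idempotent when unmethylated", {
  withr::with_seed(31, {
    for (i in 1:3) {
      s <- random_dna(1000)
      conv <- bisulfite_convert(s)
      expect_equal(conv, bisulfite_oracle(s))
      expect_equal(bisulfite_convert(s, "cpg_methylated"),
                   bisulfite_oracle(s, cpg_methylated = TRUE))
      # fully-converted output has no C left, so re-conversion is identity
      expect_false(grepl("C", conv, fixed = TRUE))
      expect_equal(bisulfite_convert(conv), conv)
    }
  })
})

test_that("published cytosine-free primers satisfy the strand-specific
           constraints", {
  a <- bisque_assays()
  fwd <- a$sequence[a$oligo == "forward" & a$cfree]
  rev <- a$sequence[a$oligo == "reverse" & a$cfree]
  expect_length(fwd, 2)
  expect_false(any(grepl("c", fwd)))  # forward primers contain no C
  expect_false(any(grepl("g", rev)))  # reverse primers contain no G
  # and therefore neither contains a C in its top-strand footprint test:
  # a planted template accepts both through the scanner
  tpl <- toupper(paste0(fwd[1], "AAAA"))
  hits <- scan_cfree_primers(tpl, c(nchar(fwd[1]), nchar(fwd[1])), "forward")
  expect_true(toupper(fwd[1]) %in% hits$sequence)
})

test_that("primer scans are exhaustive and equal brute-force enumeration", {
  withr::with_seed(32, {
    s <- random_dna(500)
    for (ori in c("forward", "reverse")) {
      got <- scan_cfree_primers(s, c(18, 22), ori)
      # brute force over every window
      expected <- list()
      for (w in 18:22) {
        for (st in 0:(nchar(s) - w)) {
          win <- substr(s, st + 1, st + w)
          if (!grepl("C", win, fixed = TRUE)) {
            primer <- if (ori == "forward") win else revcomp_chr(win)
            expected[[length(expected) + 1]] <- c(st, w, primer)
          }
        }
      }
      expect_equal(nrow(got), length(expected))
      if (length(expected) > 0) {
        exp_keys <- sort(vapply(expected, function(e)
          paste(e[1], e[2], e[3]), character(1)))
        got_keys <- sort(paste(got$start, got$length, got$sequence))
        expect_equal(got_keys, exp_keys)
      }
    }
  })
  # a window containing a C never qualifies as a forward primer
  expect_equal(nrow(scan_cfree_primers("AACAATTAAT", c(10, 10), "forward")), 0)
  expect_equal(nrow(scan_cfree_primers(strrep("C", 60), c(18, 25), "forward")), 0)
})

test_that("discrimination-probe scans find exactly single non-CpG-C windows", {
  a <- bisque_assays()
  probe_c <- toupper(a$sequence[a$oligo == "probe_C"])
  # the published probe has exactly one C and that C is not followed by G
  expect_equal(lengths(regmatches(probe_c, gregexpr("C", probe_c))), 1)
  cpos <- regexpr("C", probe_c)
  expect_false(substr(probe_c, cpos + 1, cpos + 1) == "G")
  # embedded in context it is recovered by the scanner with the right pair
  tpl <- paste0("AAATTT", probe_c, "TTAAA")
  got <- scan_discrimination_probes(tpl, c(19, 19))
  hit <- got[got$seq_c == probe_c, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$seq_t, toupper(a$sequence[a$oligo == "probe_T"]))

  # two Cs in a window disqualify it
  expect_equal(nrow(scan_discrimination_probes("AACCAAAAAAAAAAA", c(15, 15))), 0)

  withr::with_seed(33, {
    s <- random_dna(400)
    got <- scan_discrimination_probes(s, c(16, 18))
    chars <- strsplit(s, "")[[1]]
    expected <- 0
    for (w in 16:18) {
      for (st in 0:(nchar(s) - w)) {
        win <- chars[(st + 1):(st + w)]
        cp <- which(win == "C")
        if (length(cp) != 1) next
        ap <- st + cp
        if (ap < nchar(s) && chars[ap + 1] == "G") next
        expected <- expected + 1
      }
    }
    expect_equal(nrow(got), expected)
    # every reported window really has exactly one C, in non-CpG context
    expect_true(all(vapply(got$seq_c, function(p)
      lengths(regmatches(p, gregexpr("C", p))) == 1, logical(1))))
    expect_equal(got$seq_t, gsub("C", "T", got$seq_c, fixed = TRUE),
                 ignore_attr = TRUE)
  })
})

test_that("in-silico PCR recovers planted amplicons with inclusive sizing", {
  withr::with_seed(34, {
    f <- random_dna(22, c("A", "G", "T"))
    r <- random_dna(22, c("A", "C", "T"))
    tpl <- paste0(f, random_dna(10), revcomp_chr(r))
    got <- in_silico_pcr(f, r, tpl)
    expect_equal(nrow(got), 1)
    expect_equal(got$length, 54)
    expect_equal(got$sequence, tpl)

    # planted at known offsets in a longer template, two copies
    pre <- random_dna(40); mid <- random_dna(35); post <- random_dna(25)
    unit <- paste0(f, random_dna(30), revcomp_chr(r))
    tpl2 <- paste0(pre, unit, mid, unit, post)
    got2 <- in_silico_pcr(f, r, tpl2, max_product = 90)
    expect_equal(sort(got2$start), c(40, 40 + nchar(unit) + 35))
    expect_true(all(got2$length == nchar(unit)))
  })
  expect_equal(nrow(in_silico_pcr("AAAA", "TTTT", "GGGGGGGG")), 0)
})

test_that("degenerate bases expand to the full concrete set", {
  expect_equal(expand_degenerate("AYT"), c("ACT", "ATT"))
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_equal(expand_degenerate("YY"), c("CC", "CT", "TC", "TT"))
  expect_equal(sort(expand_degenerate("NN")),
               sort(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                    paste0))))
  expect_error(expand_degenerate(strrep("N", 8), max_expansion = 100),
               "exceeds")
  expect_error(expand_degenerate("AZ"), "non-IUPAC")
})

test_that("a cytosine-free primer anneals identically to converted and
           unconverted templates", {
  withr::with_seed(35, {
    # random context with a guaranteed C-free island planted inside
    s <- paste0(random_dna(140), random_dna(24, c("A", "G", "T")),
                random_dna(140))
    conv <- bisulfite_convert(s)
    fwd <- scan_cfree_primers(s, c(18, 20), "forward")
    expect_gt(nrow(fwd), 0)
    # every C-free window of the reference is unchanged by conversion,
    # so it matches the converted template at the same coordinates
    for (i in seq_len(min(nrow(fwd), 10))) {
      expect_equal(substr(conv, fwd$start[i] + 1, fwd$end[i]),
                   fwd$sequence[i])
    }
  })
})

test_that("FASTA references round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr_test", "ACGTACGTAAAT", ">other", "ggttaa"), f)
  refs <- read_reference_fasta(f)
  expect_equal(refs[["chr_test"]], "ACGTACGTAAAT")
  expect_equal(refs[["other"]], "GGTTAA")
})
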
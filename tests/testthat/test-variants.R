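# HGVS-lite classification and truncating/nontruncating grouping

test_that("protein substitutions parse to type, codon and amino acids", {
  cases <- list(
    list(p = "p.Arg167Trp", type = "missense", codon = 167L,
         ref = "R", alt = "W"),
    list(p = "p.Arg161Ter", type = "stop_gained", codon = 161L,
         ref = "R", alt = "*"),
    list(p = "p.Tyr98His", type = "missense", codon = 98L,
         ref = "Y", alt = "H"),
    list(p = "p.R167W", type = "missense", codon = 167L,
         ref = "R", alt = "W"),
    list(p = "p.Arg167=", type = "synonymous", codon = 167L,
         ref = "R", alt = "R"),
    list(p = "p.Met1Leu", type = "start_lost", codon = 1L,
         ref = "M", alt = "L"),
    list(p = "p.Leu89fs", type = "frameshift", codon = 89L,
         ref = "L", alt = NA_character_),
    list(p = "p.Arg82GlyfsTer10", type = "frameshift", codon = 82L,
         ref = "R", alt = NA_character_),
    list(p = "p.Phe76del", type = "inframe_indel", codon = 76L,
         ref = "F", alt = NA_character_),
    list(p = "p.Ter214GlnextTer17", type = "stop_lost",
         codon = NA_integer_, ref = NA_character_, alt = NA_character_))
  for (cs in cases) {
    ann <- classifyVariant(hgvs_p = cs$p)
    expect_equal(ann$variant_type, cs$type, info = cs$p)
    expect_equal(ann$codon, cs$codon, info = cs$p)
    expect_equal(ann$ref_aa, cs$ref, info = cs$p)
    expect_equal(ann$alt_aa, cs$alt, info = cs$p)
  }
})

test_that("coding-level patterns classify splice, intron, UTR and indels", {
  expect_equal(classifyVariant(hgvs_c = "c.340+1G>A")$variant_type,
               "splice_site")
  expect_true(is.na(classifyVariant(hgvs_c = "c.340+1G>A")$codon))
  expect_equal(classifyVariant(hgvs_c = "c.341-2A>G")$variant_type,
               "splice_site")
  expect_equal(classifyVariant(hgvs_c = "c.340+8G>A")$variant_type,
               "intron")
  expect_equal(classifyVariant(hgvs_c = "c.-75C>T")$variant_type, "utr")
  expect_equal(classifyVariant(hgvs_c = "c.*12A>G")$variant_type, "utr")
  expect_equal(classifyVariant(hgvs_c = "c.227_229del")$variant_type,
               "inframe_indel")
  expect_equal(classifyVariant(hgvs_c = "c.227_230del")$variant_type,
               "frameshift")
  expect_equal(classifyVariant(hgvs_c = "c.1_300del")$variant_type,
               "deletion")
  expect_equal(classifyVariant(hgvs_c = "c.341-?_463+?del")$variant_type,
               "exon_loss")
  expect_equal(classifyVariant(hgvs_c = "c.100_105delinsAT")$variant_type,
               "delins")
})

test_that("declared type is the fallback and missense requires aa fields", {
  expect_equal(classifyVariant(declared_type = "exon loss variant"
                               )$variant_type, "exon_loss")
  expect_equal(classifyVariant(hgvs_c = "garbled",
                               declared_type = "missense")$variant_type,
               "missense")
  # unparseable with no declared type degrades to unknown, not an error
  expect_equal(classifyVariant(hgvs_c = "g.10delinsNN?x")$variant_type,
               "delins")
  expect_equal(classifyVariant(hgvs_p = "p.???")$variant_type, "unknown")
  # no descriptor at all is a contract violation
  expect_error(classifyVariant(), "no variant descriptor")
  # out-of-range codon names the offender
  expect_error(classifyVariant(hgvs_p = "p.Arg500Trp"), "codon")
  ann <- classifyVariant(hgvs_p = "p.Arg167Trp")
  expect_false(is.na(ann$ref_aa) || is.na(ann$alt_aa) || is.na(ann$codon))
})

test_that("variant grouping is total and matches the published scheme", {
  expect_equal(groupVariant("stop_gained"), "truncating")
  expect_equal(groupVariant("missense"), "nontruncating")
  expect_equal(groupVariant("synonymous"), "excluded")
  truncating <- c("stop_gained", "frameshift", "deletion", "exon_loss",
                  "splice_site", "start_lost")
  nontrunc <- c("missense", "inframe_indel", "delins", "stop_lost")
  excluded <- c("synonymous", "utr", "intron", "unknown")
  all_types <- c(truncating, nontrunc, excluded)
  got <- groupVariant(all_types)
  expect_equal(got, c(rep("truncating", length(truncating)),
                      rep("nontruncating", length(nontrunc)),
                      rep("excluded", length(excluded))))
  expect_error(groupVariant("nonsense_type"), "unknown variant type")
})

test_that("grouping after classification is total on any descriptor mix", {
  descs <- data.frame(
    hgvs_c = c("c.340+1G>A", NA, "c.-10G>A", NA, "c.227_229del", NA),
    hgvs_p = c(NA, "p.Arg167Trp", NA, "p.Leu89fs", NA, NA),
    declared = c(NA, NA, NA, NA, NA, "deletion"),
    stringsAsFactors = FALSE)
  ann <- classifyVariant(descs$hgvs_c, descs$hgvs_p, descs$declared)
  grp <- groupVariant(ann$variant_type)
  expect_true(all(grp %in% c("truncating", "nontruncating", "excluded")))
})
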
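# SMILES used to build SDF fixtures at test time (Open Babel writes the
# V2000 blocks). Chosen to exercise each cleaning rule.
SMI <- list(
  ethanol = "CCO",
  hexane = "CCCCCC",               # hydrocarbon
  benzene = "c1ccccc1",            # aromatic hydrocarbon
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  fluorobenzene = "Fc1ccccc1",     # F is outside the element whitelist
  mixture2 = "CCO.CC(=O)O",        # two fragments, whitelisted elements
  mixture3 = "C.CC.CCC",           # three fragments, one record
  phenol = "c1ccccc1O"
)

test_that("SDF parsing keeps valid records and counts broken ones", {
  p <- smiles_sdf(c(SMI$ethanol, SMI$aspirin, SMI$phenol))
  mols <- read_sdf(p)
  expect_equal(nrow(mols), 3)
  expect_equal(mols$record_id, 1:3)
  expect_equal(attr(mols, "parse_failures"), 0)
  append_record(p, corrupt_sdf_record())
  mols2 <- read_sdf(p)
  expect_equal(nrow(mols2), 3)
  expect_equal(attr(mols2, "parse_failures"), 1)
  expect_equal(attr(mols2, "n_raw"), 4)
  expect_error(read_sdf(tempfile()), "not found")
})

test_that("benzene parses to the {C, H} element set and a benzene InChI", {
  mols <- read_sdf(smiles_sdf(SMI$benzene))
  expect_setequal(mols$elements[[1]], c("C", "H"))
  # cross-check the canonical identifier against the known structure
  expect_equal(mols$canonical_id[1], "InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H")
  expect_equal(mols$n_fragments[1], 1)
})

test_that("the element filter removes hydrocarbons and foreign elements", {
  mols <- read_sdf(smiles_sdf(c(SMI$hexane, SMI$fluorobenzene,
                                SMI$aspirin, SMI$benzene)))
  out <- element_filter(mols)
  expect_equal(out$kept$record_id, 3)          # aspirin survives
  expect_equal(out$removed$record_id, c(1, 2, 4))
  expect_equal(out$removed$reason, c("hydrocarbon", "element",
                                     "hydrocarbon"))
})

test_that("multi-fragment records are removed whole", {
  mols <- read_sdf(smiles_sdf(c(SMI$mixture2, SMI$ethanol, SMI$mixture3)))
  expect_equal(mols$n_fragments, c(2, 1, 3))
  out <- remove_mixtures(mols)
  expect_equal(out$kept$record_id, 2)
  expect_equal(nrow(out$removed), 2)   # one removal per record
})

test_that("deduplication keeps first occurrences and empties cross-set hits", {
  pos <- read_sdf(smiles_sdf(c(SMI$aspirin, SMI$ethanol, SMI$aspirin)),
                  "positive")
  neg <- read_sdf(smiles_sdf(c(SMI$phenol, SMI$ethanol, SMI$phenol)),
                  "negative")
  dd <- deduplicate(pos, neg)
  expect_equal(dd$positive$record_id, c(1, 2))      # second aspirin gone
  expect_equal(dd$negative$record_id, 1)            # dup phenol + shared ethanol gone
  expect_equal(dd$counts$removed_within_positive, 1)
  expect_equal(dd$counts$removed_within_negative, 1)
  expect_equal(dd$counts$removed_cross_set, 1)
  # disjoint deduplicated sets pass through unchanged
  dd2 <- deduplicate(dd$positive, dd$negative)
  expect_equal(dd2$positive$canonical_id, dd$positive$canonical_id)
  expect_equal(unlist(dd2$counts), c(removed_within_positive = 0,
                                     removed_within_negative = 0,
                                     removed_cross_set = 0))
})

test_that("the full pipeline reconciles its report and is idempotent", {
  ppath <- smiles_sdf(c(SMI$aspirin, SMI$hexane, SMI$ethanol, SMI$aspirin))
  append_record(ppath, corrupt_sdf_record())
  npath <- smiles_sdf(c(SMI$phenol, SMI$mixture2, SMI$ethanol,
                        SMI$fluorobenzene))
  pos <- read_sdf(ppath, "positive")
  neg <- read_sdf(npath, "negative")
  cleaned <- clean_molecules(pos, neg)
  rep <- cleaned$report
  # counts always reconcile: input = output + removals + failures
  removal_cols <- c("parse_failures", "removed_hydrocarbon",
                    "removed_element", "removed_mixture",
                    "removed_duplicate_within", "removed_cross_set")
  expect_equal(rep$input_count,
               rep$output_count + rowSums(rep[removal_cols]))
  expect_equal(rep$output_count, c(2, 1))
  # rerunning the pipeline on its own output removes nothing
  pdir <- withr::local_tempfile(fileext = ".sdf")
  ndir <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(cleaned$positive, pdir)
  write_sdf(cleaned$negative, ndir)
  again <- clean_molecules(read_sdf(pdir, "positive"),
                           read_sdf(ndir, "negative"))
  expect_equal(again$report$output_count, rep$output_count)
  expect_equal(sum(again$report[removal_cols]), 0)
  # the JSON report writes and reads back
  jpath <- withr::local_tempfile(fileext = ".json")
  write_cleaning_report(rep, jpath)
  expect_equal(jsonlite::fromJSON(jpath)$output_count, c(2, 1))
})

test_that("cleaning results do not depend on input file chunking", {
  all_smi <- c(SMI$aspirin, SMI$hexane, SMI$ethanol, SMI$phenol)
  whole <- read_sdf(smiles_sdf(all_smi), "positive")
  part1 <- read_sdf(smiles_sdf(all_smi[1:2]), "positive")
  part2 <- read_sdf(smiles_sdf(all_smi[3:4]), "positive")
  merged <- dplyr::bind_rows(part1, part2)
  ops <- function(m) {
    k <- remove_mixtures(element_filter(m)$kept)$kept
    k$canonical_id[!duplicated(k$canonical_id)]
  }
  expect_equal(ops(merged), ops(whole))
})
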
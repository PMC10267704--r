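test_that("read-support quality predicate enforces all three bounds", {
  cases <- data.frame(
    genotype = "het",
    total_reads = c(10L, 9L, 100L, 100L, 25L),
    variant_reads = c(5L, 9L, 19L, 20L, 4L)
  )
  # boundary: 10 reads, 5 variant reads, 50% fraction passes;
  # 9 total fails depth; 19/100 fails the 20% fraction; 20/100 passes;
  # 4 variant reads fails the absolute bound
  expect_identical(is_high_confidence(cases),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(
    is_high_confidence(data.frame(genotype = "het", total_reads = 0L,
                                  variant_reads = 0L)),
    "zero total reads")
  # missing genotype with zero reads is permitted (and fails the cut)
  expect_false(is_high_confidence(data.frame(genotype = "missing",
                                             total_reads = 0L,
                                             variant_reads = 0L)))
})

test_that("protein-altering classification is truncation-or-conserved-missense", {
  v <- rbind(
    variant_row(consequence = "frameshift", phylop = NA_real_),
    variant_row(consequence = "nonsense", phylop = NA_real_),
    variant_row(consequence = "canonical_splice", phylop = NA_real_),
    variant_row(consequence = "missense", phylop = 3.0),
    variant_row(consequence = "missense", phylop = 2.9),
    variant_row(consequence = "missense", phylop = NA_real_),
    variant_row(consequence = "synonymous", phylop = 8),
    variant_row(consequence = "other", phylop = 8)
  )
  expect_identical(is_protein_altering(v),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # the missing-phyloP missense default (exclude) can be overridden
  expect_true(is_protein_altering(v, missense_missing_phylop = "include")[6])
})

test_that("rarity removes MAF strictly above the cut and in-house hits", {
  v <- rbind(
    variant_row(),                                     # all absent
    variant_row(maf_exac = 0.002),                     # one panel too common
    variant_row(maf_dbsnp = 0.001, maf_esp = 0.001,
                maf_exac = 0.001, maf_1kg = 0.001),    # exactly at the cut
    variant_row(inhouse_present = TRUE),
    variant_row(maf_1kg = 0.0005)
  )
  expect_identical(is_rare(v), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # in-house requirement can be lifted
  expect_true(is_rare(v, rarity_thresholds(require_inhouse_absent = FALSE))[4])
})

test_that("family sharing needs every index patient as a confident carrier", {
  ped <- two_family_pedigree()
  v <- "chr1:100A>T"
  both_het <- rbind(call_row(v, "FA-1"), call_row(v, "FA-2"))
  one_ref <- rbind(call_row(v, "FA-1"),
                   call_row(v, "FA-2", genotype = "hom_ref", variant_reads = 0L))
  one_missing <- rbind(call_row(v, "FA-1"),
                       call_row(v, "FA-2", genotype = "missing",
                                total_reads = 0L, variant_reads = 0L))
  one_lowq <- rbind(call_row(v, "FA-1"),
                    call_row(v, "FA-2", total_reads = 8L, variant_reads = 4L))
  no_record <- call_row(v, "FA-1")
  expect_true(shared_in_family(v, both_het, ped))
  expect_false(shared_in_family(v, one_ref, ped))
  expect_false(shared_in_family(v, one_missing, ped))
  expect_false(shared_in_family(v, one_lowq, ped))
  expect_false(shared_in_family(v, no_record, ped))
  # sharing in one family suffices; restricting to the other family fails
  expect_true(shared_in_family(v, both_het, ped, family = "FA"))
  expect_false(shared_in_family(v, both_het, ped, family = "FB"))
  # hom_alt counts as carrying
  expect_true(shared_in_family(
    v, rbind(call_row(v, "FA-1", genotype = "hom_alt", variant_reads = 28L),
             call_row(v, "FA-2")), ped))
})

test_that("candidate categories resolve panel membership before novelty", {
  panels <- test_panels()
  v <- rbind(
    variant_row(gene = "NOD2", consequence = "frameshift"),
    variant_row(gene = "BTK", consequence = "missense", phylop = 5),
    variant_row(gene = "SIRPB1", consequence = "frameshift"),
    variant_row(gene = "UNLISTED1", consequence = "frameshift"),
    variant_row(gene = "UNLISTED2", consequence = "synonymous")
  )
  expect_identical(assign_candidate_category(v, panels),
                   c("gwas", "pid", "pathway", "novel", "none"))
})

test_that("the cascade recovers a planted variant from designed background", {
  ped <- two_family_pedigree()
  panels <- test_panels()
  planted <- variant_row(variant_id = "chr7:1000G>GA", chrom = "chr7",
                         pos = 1000L, ref = "G", alt = "GA", gene = "SIRPB1",
                         consequence = "frameshift", phylop = NA_real_)
  bg <- rbind(
    variant_row("chr1:1A>T", pos = 1L, gene = "B1", consequence = "other"),
    variant_row("chr1:2A>T", pos = 2L, gene = "B2", consequence = "synonymous"),
    variant_row("chr1:3A>T", pos = 3L, gene = "B3", consequence = "missense",
                phylop = 1.2),
    variant_row("chr1:4A>T", pos = 4L, gene = "B4", consequence = "missense",
                phylop = 6, maf_exac = 0.01),
    variant_row("chr1:5A>T", pos = 5L, gene = "B5", consequence = "nonsense",
                inhouse_present = TRUE),
    variant_row("chr1:6A>T", pos = 6L, gene = "B6", consequence = "nonsense")
  )
  v <- rbind(planted, bg)
  shared_ids <- c("chr7:1000G>GA", "chr1:1A>T", "chr1:2A>T", "chr1:3A>T",
                  "chr1:4A>T", "chr1:5A>T")
  calls <- do.call(rbind, c(
    lapply(shared_ids, function(id) rbind(call_row(id, "FA-1"),
                                          call_row(id, "FA-2"))),
    # chr1:6 fails sharing only: a single carrier
    list(call_row("chr1:6A>T", "FA-1"))
  ))
  rep <- run_cascade(v, calls, ped, panels)
  expect_identical(rep$variants$variant_id, "chr7:1000G>GA")
  expect_identical(rep$variants$category, "pathway")
  expect_identical(rep$stages$stage[1], "all")
  expect_equal(rep$stages$n[1], 7)
  # each background variant drops at its designed stage
  excl <- setNames(rep$exclusions$stage, rep$exclusions$variant_id)
  expect_identical(unname(excl["chr1:1A>T"]), "coding_quality")
  expect_identical(unname(excl["chr1:2A>T"]), "nonsynonymous")
  expect_identical(unname(excl["chr1:3A>T"]), "family_shared_protein_altering")
  expect_identical(unname(excl["chr1:6A>T"]), "family_shared_protein_altering")
  expect_identical(unname(excl["chr1:4A>T"]), "rare")
  expect_identical(unname(excl["chr1:5A>T"]), "rare")
})

test_that("single-variant rarity delta moves exactly one count", {
  ped <- two_family_pedigree()
  panels <- test_panels()
  v <- rbind(
    variant_row("chr7:1000G>GA", "chr7", 1000L, "G", "GA", gene = "SIRPB1",
                consequence = "frameshift", phylop = NA_real_),
    variant_row("chr7:2000G>GA", "chr7", 2000L, "G", "GA", gene = "TLR4",
                consequence = "frameshift", phylop = NA_real_,
                maf_exac = 0.01)
  )
  calls <- do.call(rbind, lapply(v$variant_id, function(id) {
    rbind(call_row(id, "FA-1"), call_row(id, "FA-2"))
  }))
  rep <- run_cascade(v, calls, ped, panels)
  st <- setNames(rep$stages$n, rep$stages$stage)
  expect_equal(unname(st["rare"]),
               unname(st["family_shared_protein_altering"]) - 1)
  expect_identical(rep$variants$variant_id, "chr7:1000G>GA")
})

test_that("stage counts never increase and filters are idempotent", {
  for (seed in c(3L, 17L)) {
    sim <- simulate_families(family_sim_config(seed = seed,
                                               n_background_variants = 120L))
    rep <- run_cascade(sim$variants, sim$calls, sim$pedigree, sim$panels)
    expect_true(all(diff(rep$stages$n) <= 0))
    # re-running the cascade on its own survivors changes nothing
    again <- run_cascade(rep$variants, sim$calls, sim$pedigree, sim$panels)
    expect_identical(again$variants$variant_id, rep$variants$variant_id)
    expect_true(all(again$stages$n == nrow(rep$variants)))
  }
})

test_that("sharing and rarity commute and survivors satisfy every predicate", {
  sim <- simulate_families(family_sim_config(seed = 29L,
                                             n_background_variants = 150L))
  v <- sim$variants
  pa <- is_protein_altering(v)
  sh <- unname(shared_in_family(v$variant_id, sim$calls, sim$pedigree))
  ra <- is_rare(v)
  order_a <- v$variant_id[(pa & sh) & ra]
  order_b <- v$variant_id[ra & (pa & sh)]
  expect_identical(order_a, order_b)

  rep <- run_cascade(v, sim$calls, sim$pedigree, sim$panels)
  # direct predicate re-evaluation on the final set, outside the cascade
  fin <- rep$variants
  expect_true(all(fin$consequence %in% c("missense", "nonsense", "frameshift",
                                         "canonical_splice")))
  expect_true(all(is_protein_altering(fin)))
  expect_true(all(is_rare(fin)))
  expect_true(all(shared_in_family(fin$variant_id, sim$calls, sim$pedigree)))
  expect_true(all(assign_candidate_category(fin, sim$panels) != "none"))
})

test_that("planted variants passing every predicate are always recovered", {
  hits <- 0L
  for (seed in 1:100) {
    planted <- data.frame(
      gene = "SIRPB1", consequence = "frameshift", phylop = NA_real_,
      maf_dbsnp = NA_real_, maf_esp = NA_real_, maf_exac = NA_real_,
      maf_1kg = NA_real_, inhouse_present = FALSE, family = "F02",
      stringsAsFactors = FALSE)
    sim <- simulate_families(family_sim_config(
      seed = seed, n_families = 4L, n_background_variants = 60L,
      planted_variants = planted))
    rep <- run_cascade(sim$variants, sim$calls, sim$pedigree, sim$panels)
    want <- sim$truth$variant_id[sim$truth$expected_survive]
    expect_setequal(rep$variants$variant_id, want)
    hits <- hits + length(want)
  }
  expect_gt(hits, 0L)
})

test_that("degenerate cascade inputs behave as specified", {
  ped <- two_family_pedigree()
  empty_ped <- ped[0, ]
  v <- variant_row()
  expect_error(run_cascade(v, call_row(v$variant_id, "FA-1"), empty_ped,
                           test_panels()),
               "empty")
  rep <- run_cascade(v[0, ], call_row(v$variant_id, "FA-1")[0, ], ped,
                     test_panels())
  expect_true(all(rep$stages$n == 0))
})

test_that("pass and cap lists restrict the final set when supplied", {
  ped <- two_family_pedigree()
  v <- rbind(
    variant_row("chr7:1000G>GA", "chr7", 1000L, "G", "GA", gene = "SIRPB1",
                consequence = "frameshift", phylop = NA_real_),
    variant_row("chr7:2000G>GA", "chr7", 2000L, "G", "GA", gene = "TLR4",
                consequence = "frameshift", phylop = NA_real_)
  )
  calls <- do.call(rbind, lapply(v$variant_id, function(id) {
    rbind(call_row(id, "FA-1"), call_row(id, "FA-2"))
  }))
  rep <- run_cascade(v, calls, ped, test_panels(),
                     pass_list = "chr7:1000G>GA")
  expect_identical(rep$variants$variant_id, "chr7:1000G>GA")
  expect_identical(rep$stages$stage[nrow(rep$stages)], "pass_list")
})

test_that("cascade reports serialize to TSV and JSON", {
  sim <- simulate_families(family_sim_config(seed = 5L,
                                             n_background_variants = 30L))
  rep <- run_cascade(sim$variants, sim$calls, sim$pedigree, sim$panels)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "stages.tsv"); js <- file.path(dir, "detail.json")
  write_cascade_report(rep, tsv, js)
  back <- read.delim(tsv)
  expect_equal(back$n, rep$stages$n)
  detail <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(detail$variants), nrow(rep$variants))
})
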
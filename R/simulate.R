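# Run expr under a temporary RNG state seeded with `seed`; the ambient
# .Random.seed is restored afterwards so simulation never leaks into or
# depends on global state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Built-in candidate-gene panels for simulation
#'
#' Small illustrative panels used by the family simulator: genes at known
#' IBD GWAS loci, primary immunodeficiency genes, and innate-immune /
#' neutrophil-degranulation pathway genes. Real analyses should supply their
#' own curated panels via [read_gene_panels()].
#'
#' @return A [gene_panels()] object.
#' @export
default_sim_panels <- function() {
  gene_panels(
    gwas = c("NOD2", "TNFSF15", "LSP1", "ZPBP2", "SDCCAG3", "MUC19",
             "IL23R", "ATG16L1", "IRGM", "TYK2"),
    pid = c("BTK", "WAS", "FOXP3", "IL10RA", "IL10RB", "CYBB", "XIAP",
            "LRBA", "STAT1"),
    pathway = c("SIRPB1", "TLR4", "NLRP3", "CARD9", "ITGAM", "NCF4",
                "MPO", "ELANE", "FCGR3B")
  )
}

default_planted_variants <- function() {
  data.frame(
    gene = "SIRPB1", consequence = "frameshift", phylop = NA_real_,
    maf_dbsnp = NA_real_, maf_esp = NA_real_, maf_exac = NA_real_,
    maf_1kg = NA_real_, inhouse_present = FALSE, family = "F07",
    stringsAsFactors = FALSE
  )
}

#' Configuration of the family cohort simulator
#'
#' Defines the synthetic multi-family sequencing cohort: `n_families`
#' families of `members_per_family` affected index patients each (the
#' default, 12 families of 2, is the scale of a family-based genome study),
#' `n_background_variants` background variants each constructed to fail
#' exactly one cascade predicate, and `planted_variants` that the designated
#' family shares. Read depths follow a negative-binomial count model with
#' mean `depth_mean`; reference-panel frequencies follow a mixture of a
#' point mass at "absent" (probability `maf_absent_prob`) and a log-uniform
#' draw over `maf_range`.
#'
#' @param n_families,members_per_family Cohort dimensions (default 12 x 2).
#' @param n_background_variants Number of designed-failure background
#'   variants (default 500).
#' @param planted_variants Data frame with columns `gene`, `consequence`,
#'   `phylop`, the four `maf_*` columns, `inhouse_present`, and `family`
#'   (the id of the family sharing the variant, or `NA` to plant it in a
#'   single carrier only). Default: one shared frameshift in an
#'   innate-immune pathway gene.
#' @param maf_absent_prob,maf_range Mixture of the background frequency
#'   model.
#' @param depth_mean,depth_size Negative-binomial read-depth model.
#' @param seed Mandatory integer seed.
#' @return Object of class `family_sim_config`.
#' @export
family_sim_config <- function(n_families = 12L, members_per_family = 2L,
                              n_background_variants = 500L,
                              planted_variants = default_planted_variants(),
                              maf_absent_prob = 0.6,
                              maf_range = c(1e-5, 0.05),
                              depth_mean = 30, depth_size = 8,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_families >= 1L, members_per_family >= 1L,
            n_background_variants >= 0L,
            maf_absent_prob >= 0, maf_absent_prob <= 1,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 1, depth_mean > 0, depth_size > 0)
  n_planted <- if (is.null(planted_variants)) 0L else nrow(planted_variants)
  if (n_background_variants + n_planted == 0L) {
    stop("config requests no variants at all", call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    members_per_family = as.integer(members_per_family),
    n_background_variants = as.integer(n_background_variants),
    planted_variants = planted_variants,
    maf_absent_prob = maf_absent_prob, maf_range = maf_range,
    depth_mean = depth_mean, depth_size = depth_size,
    seed = as.integer(seed)
  ), class = "family_sim_config")
}

# Failure modes assigned to background variants; each guarantees exactly one
# cascade predicate fails (values are drawn safely away from thresholds).
background_modes <- function() {
  c("not_coding", "low_quality", "synonymous", "low_phylop_missense",
    "not_shared", "common_maf", "inhouse")
}

# Read support that passes the default quality thresholds with margin.
good_carrier_reads <- function(n, mu, size) {
  tot <- pmax(12L, stats::rnbinom(n, mu = mu, size = size))
  vr <- stats::rbinom(n, tot, 0.5)
  vr <- pmin(tot, pmax(vr, 5L, ceiling(0.25 * tot)))
  data.frame(total = tot, variant = vr)
}

#' Simulate an annotated family sequencing cohort with known truth
#'
#' Generates, from one seeded random source, the complete post-calling input
#' of the prioritization cascade: an annotated variant table, per-sample
#' calls with read support, a pedigree, candidate-gene panels, and a truth
#' manifest. Planted variants are carried (heterozygous, with read support
#' satisfying the quality model) by every index patient of their designated
#' family. Each background variant is assigned one failure mode — outside
#' the coding regions, read support below the quality cut, synonymous,
#' missense at a weakly conserved position, carried by only one index
#' patient, common in a reference panel, or present in the in-house
#' database — and passes every other predicate, so the set of variants
#' expected to survive the cascade is known exactly by construction and
#' recorded in the manifest with per-variant failure reasons.
#'
#' @param cfg A [family_sim_config()].
#' @return Object of class `family_sim`: list with `variants`, `calls`,
#'   `pedigree`, `panels`, `truth` (data frame `variant_id`, `planted`,
#'   `expected_survive`, `fail_reason`), and `config`.
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "family_sim_config"))
  with_seed(cfg$seed, {
    fam_ids <- sprintf("F%02d", seq_len(cfg$n_families))
    pedigree <- data.frame(
      family_id = rep(fam_ids, each = cfg$members_per_family),
      sample_id = paste0(rep(fam_ids, each = cfg$members_per_family), "-",
                         seq_len(cfg$members_per_family)),
      affected = TRUE, index = TRUE,
      kinship = rep(sample(c("siblings", "identical twins", "fraternal twins",
                             "parent and child"), cfg$n_families,
                           replace = TRUE),
                    each = cfg$members_per_family),
      stringsAsFactors = FALSE
    )
    samples <- pedigree$sample_id

    planted <- cfg$planted_variants
    n_pl <- if (is.null(planted)) 0L else nrow(planted)
    if (n_pl > 0L) {
      unknown <- setdiff(stats::na.omit(as.character(planted$family)), fam_ids)
      if (length(unknown)) {
        stop("planted variant family not in the simulated cohort: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
    n_bg <- cfg$n_background_variants
    n <- n_pl + n_bg

    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sort(sample.int(2e8L, n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    mode <- if (n_bg > 0L) sample(rep_len(background_modes(), n_bg)) else character()

    csq <- character(n); phylop <- rep(NA_real_, n)
    gene <- character(n); inhouse <- rep(FALSE, n)
    maf <- matrix(NA_real_, n, 4L,
                  dimnames = list(NULL, c("maf_dbsnp", "maf_esp", "maf_exac",
                                          "maf_1kg")))
    share_family <- rep(NA_character_, n)
    solo_carrier <- rep(NA_character_, n)

    # annotation-style precision (6 significant digits for frequencies,
    # 3 decimals for conservation scores) so serialized values round-trip
    rlogunif <- function(k, lo, hi) {
      signif(exp(stats::runif(k, log(lo), log(hi))), 6)
    }
    rare_maf <- function(k) {
      # passes the rarity filter: absent, or at most half the default cut
      out <- rep(NA_real_, k)
      draw <- stats::runif(k) > cfg$maf_absent_prob
      out[draw] <- rlogunif(sum(draw), cfg$maf_range[1L],
                            min(5e-4, cfg$maf_range[2L]))
      out
    }
    pass_csq <- function(k) {
      # protein-altering consequences for variants that must survive stage 3
      cs <- sample(c("frameshift", "nonsense", "canonical_splice", "missense"),
                   k, replace = TRUE)
      list(csq = cs,
           phylop = ifelse(cs == "missense",
                           round(stats::runif(k, 3.5, 9), 3), NA_real_))
    }

    if (n_pl > 0L) {
      i <- seq_len(n_pl)
      gene[i] <- toupper(planted$gene)
      csq[i] <- planted$consequence
      phylop[i] <- planted$phylop
      for (col in colnames(maf)) {
        if (col %in% names(planted)) maf[i, col] <- planted[[col]]
      }
      inhouse[i] <- as_flag(planted$inhouse_present)
      share_family[i] <- as.character(planted$family)
    }
    if (n_bg > 0L) {
      i <- n_pl + seq_len(n_bg)
      gene[i] <- sprintf("BGG%04d", seq_len(n_bg))
      pc <- pass_csq(n_bg)
      csq[i] <- pc$csq; phylop[i] <- pc$phylop
      for (col in colnames(maf)) maf[i, col] <- rare_maf(n_bg)
      share_family[i] <- sample(fam_ids, n_bg, replace = TRUE)

      csq[i][mode == "not_coding"] <- "other"
      phylop[i][mode == "not_coding"] <- NA_real_
      csq[i][mode == "synonymous"] <- "synonymous"
      phylop[i][mode == "synonymous"] <- NA_real_
      lm <- mode == "low_phylop_missense"
      csq[i][lm] <- "missense"
      phylop[i][lm] <- round(stats::runif(sum(lm), 0, 2.5), 3)
      cm <- mode == "common_maf"
      panel_col <- sample(colnames(maf), sum(cm), replace = TRUE)
      maf[i[cm], ] <- NA_real_
      maf[cbind(i[cm], match(panel_col, colnames(maf)))] <-
        rlogunif(sum(cm), 2e-3, cfg$maf_range[2L])
      inhouse[i][mode == "inhouse"] <- TRUE
      ns <- mode == "not_shared"
      fam_members <- split(pedigree$sample_id, pedigree$family_id)
      solo_carrier[i][ns] <- vapply(share_family[i][ns], function(f) {
        # a single carrier breaks sharing only if the family has >1 index
        # patient; otherwise the variant gets no carrier at all
        if (length(fam_members[[f]]) > 1L) fam_members[[f]][1L]
        else NA_character_
      }, character(1L))
      share_family[i][ns] <- NA_character_
    }

    alt <- vapply(seq_len(n), function(j) {
      if (csq[j] == "frameshift") {
        if (stats::runif(1) < 0.5) {
          paste0(ref[j], sample(bases, 1L))          # 1-bp insertion
        } else {
          # represent a deletion: ref extended, alt anchor base
          ref[j] <<- paste0(ref[j], paste(sample(bases, 2L, replace = TRUE),
                                          collapse = ""))
          substr(ref[j], 1L, 1L)
        }
      } else {
        sample(setdiff(bases, substr(ref[j], 1L, 1L)), 1L)
      }
    }, character(1L))

    variants <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
      consequence = csq, phylop = phylop,
      maf_dbsnp = maf[, 1L], maf_esp = maf[, 2L], maf_exac = maf[, 3L],
      maf_1kg = maf[, 4L], inhouse_present = inhouse,
      stringsAsFactors = FALSE
    )
    variants$variant_id <- format_variant_key(variants)
    mode_full <- c(rep(NA_character_, n_pl), mode)
    if (anyDuplicated(variants$variant_id)) {
      keep <- !duplicated(variants$variant_id)
      variants <- variants[keep, , drop = FALSE]
      mode_full <- mode_full[keep]
      share_family <- share_family[keep]
      solo_carrier <- solo_carrier[keep]
      n_pl <- sum(keep[seq_len(n_pl)])
    }
    variants <- variants[, c("variant_id", setdiff(names(variants),
                                                   "variant_id"))]
    n <- nrow(variants)

    # carriers per variant
    fam_members <- split(pedigree$sample_id, pedigree$family_id)
    carriers <- vector("list", n)
    for (j in seq_len(n)) {
      if (!is.na(share_family[j]) && share_family[j] %in% names(fam_members)) {
        carriers[[j]] <- fam_members[[share_family[j]]]
      } else if (!is.na(solo_carrier[j])) {
        carriers[[j]] <- solo_carrier[j]
      } else {
        carriers[[j]] <- character()
      }
    }

    # calls: one row per variant per sample
    call_grid <- expand.grid(variant_row = seq_len(n), sample = samples,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    carrier_keys <- unlist(lapply(seq_len(n), function(j) {
      if (length(carriers[[j]])) paste(j, carriers[[j]]) else character()
    }))
    is_carrier <- paste(call_grid$variant_row, call_grid$sample) %in%
      carrier_keys
    low_q <- !is.na(mode_full[call_grid$variant_row]) &
      mode_full[call_grid$variant_row] == "low_quality"

    m <- nrow(call_grid)
    tot <- pmax(8L, stats::rnbinom(m, mu = cfg$depth_mean,
                                   size = cfg$depth_size))
    vr <- integer(m)
    gtype <- rep("hom_ref", m)

    car_ok <- which(is_carrier & !low_q)
    if (length(car_ok)) {
      rr <- good_carrier_reads(length(car_ok), cfg$depth_mean, cfg$depth_size)
      tot[car_ok] <- rr$total; vr[car_ok] <- rr$variant
      gtype[car_ok] <- "het"
    }
    car_lq <- which(is_carrier & low_q)
    if (length(car_lq)) {
      # fails the quality cut: shallow depth, a single supporting read
      tot[car_lq] <- sample(3:8, length(car_lq), replace = TRUE)
      vr[car_lq] <- 1L
      gtype[car_lq] <- "het"
    }

    calls <- data.frame(
      variant_id = variants$variant_id[call_grid$variant_row],
      sample = call_grid$sample,
      genotype = gtype, total_reads = as.integer(tot),
      variant_reads = as.integer(vr),
      stringsAsFactors = FALSE
    )

    panels <- default_sim_panels()

    planted_flag <- c(rep(TRUE, n_pl), rep(FALSE, n - n_pl))
    fail_reason <- rep(NA_character_, n)
    fail_reason[!planted_flag] <- mode_full[!planted_flag]
    if (n_pl > 0L) {
      for (j in seq_len(n_pl)) {
        fail_reason[j] <- planted_fail_reason(variants[j, ], share_family[j])
      }
    }
    truth <- data.frame(
      variant_id = variants$variant_id,
      gene = variants$gene,
      planted = planted_flag,
      expected_survive = is.na(fail_reason),
      fail_reason = fail_reason,
      stringsAsFactors = FALSE
    )

    structure(list(variants = variants, calls = calls, pedigree = pedigree,
                   panels = panels, truth = truth, config = cfg),
              class = "family_sim")
  })
}

# Expected cascade outcome of a planted variant, derived from its configured
# annotation values against the default thresholds (independent of the
# cascade engine's bookkeeping).
planted_fail_reason <- function(v, share_family) {
  if (!v$consequence %in% setdiff(consequence_classes(), "other")) {
    return("not_coding")
  }
  if (v$consequence == "synonymous") return("synonymous")
  if (v$consequence == "missense" &&
      (is.na(v$phylop) || v$phylop < 3.0)) {
    return("low_phylop_missense")
  }
  if (is.na(share_family)) return("not_shared")
  mafs <- unlist(v[c("maf_dbsnp", "maf_esp", "maf_exac", "maf_1kg")])
  if (any(!is.na(mafs) & mafs > 0.001)) return("common_maf")
  if (isTRUE(v$inhouse_present)) return("inhouse")
  NA_character_
}

#' @export
print.family_sim <- function(x, ...) {
  cat("Synthetic family cohort: ", length(unique(x$pedigree$family_id)),
      " families, ", nrow(x$pedigree), " samples, ", nrow(x$variants),
      " variants (", sum(x$truth$planted), " planted, ",
      sum(x$truth$expected_survive), " expected to survive the cascade)\n",
      sep = "")
  invisible(x)
}

#' Write a simulated family cohort to disk
#'
#' Writes the cohort as the standard files the pipeline reads back: an
#' annotated multi-sample VCF (`cohort.vcf`, annotations under the default
#' INFO keys, per-sample `GT:DP:AD`), `pedigree.tsv`, the three gene panels,
#' `annotations.tsv`, and `truth.tsv`. Output is deterministic given the
#' simulation seed, byte for byte.
#'
#' @param sim A `family_sim` from [simulate_families()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_family_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    pedigree = file.path(dir, "pedigree.tsv"),
    gwas = file.path(dir, "panel_gwas.txt"),
    pid = file.path(dir, "panel_pid.txt"),
    pathway = file.path(dir, "panel_pathway.txt"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_cohort_vcf(sim$variants, sim$calls, paths$vcf)
  write_tsv(sim$pedigree, paths$pedigree)
  writeLines(sim$panels$gwas, paths$gwas)
  writeLines(sim$panels$pid, paths$pid)
  writeLines(sim$panels$pathway, paths$pathway)
  write_tsv(sim$variants, paths$annotations)
  write_tsv(sim$truth, paths$truth)
  invisible(paths)
}

# Format one annotated cohort VCF. Absent annotation values are omitted from
# INFO (absent and zero are different states downstream).
write_cohort_vcf <- function(variants, calls, path) {
  keys <- default_annotation_keys()
  samples <- unique(calls$sample)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famrvar",
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Gene symbol\">",
            keys$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Consequence class\">",
            keys$consequence),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"phyloP conservation\">",
            keys$phylop),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"dbSNP allele frequency\">",
            keys$maf_dbsnp),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"ESP allele frequency\">",
            keys$maf_esp),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"ExAC allele frequency\">",
            keys$maf_exac),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"1000 Genomes allele frequency\">",
            keys$maf_1kg),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Present in in-house exomes\">",
            keys$inhouse),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info_of <- function(v) {
    parts <- c(
      paste0(keys$gene, "=", v$gene),
      paste0(keys$consequence, "=", v$consequence),
      if (!is.na(v$phylop)) paste0(keys$phylop, "=", format(v$phylop, digits = 6)),
      if (!is.na(v$maf_dbsnp)) paste0(keys$maf_dbsnp, "=", format(v$maf_dbsnp, digits = 6)),
      if (!is.na(v$maf_esp)) paste0(keys$maf_esp, "=", format(v$maf_esp, digits = 6)),
      if (!is.na(v$maf_exac)) paste0(keys$maf_exac, "=", format(v$maf_exac, digits = 6)),
      if (!is.na(v$maf_1kg)) paste0(keys$maf_1kg, "=", format(v$maf_1kg, digits = 6)),
      paste0(keys$inhouse, "=", as.integer(v$inhouse_present))
    )
    paste(parts, collapse = ";")
  }
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  nrec <- nrow(variants)
  pair <- paste(rep(variants$variant_id, times = length(samples)),
                rep(samples, each = nrec))
  k <- match(pair, paste(calls$variant_id, calls$sample))
  field <- ifelse(is.na(k), "./.:0:0,0",
                  sprintf("%s:%d:%d,%d", gt_map[calls$genotype[k]],
                          calls$total_reads[k],
                          calls$total_reads[k] - calls$variant_reads[k],
                          calls$variant_reads[k]))
  fmat <- matrix(field, nrow = nrec)
  info <- vapply(seq_len(nrec), function(i) info_of(variants[i, ]),
                 character(1L))
  recs <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT:DP:AD",
                apply(fmat, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Configuration of the replication cohort simulator
#'
#' Defines a synthetic case-control replication experiment. Subject carrier
#' status is Bernoulli: controls at `control_carrier_freq`, cases at the
#' probability implied by `true_odds_ratio` through the odds transform
#' `p_case = r f / (1 - f + r f)`, which makes the configured odds ratio the
#' estimand of the association module. Genotyping missingness removes each
#' subject independently with probability `missing_rate`. The defaults
#' mirror a replication cohort of 381 cases and 381 controls with a control
#' carrier frequency of 2/381 and a true odds ratio of 4.59 — the scale of a
#' rare-frameshift replication experiment.
#'
#' @param n_cases,n_controls Group sizes (defaults 381 each).
#' @param control_carrier_freq Carrier frequency among controls.
#' @param true_odds_ratio True dominant-model odds ratio (> 0).
#' @param missing_rate Per-subject genotyping failure probability.
#' @param n_variants Number of independent variants to draw (default 1).
#' @param seed Mandatory integer seed.
#' @return Object of class `replication_sim_config`.
#' @export
replication_sim_config <- function(n_cases = 381L, n_controls = 381L,
                                   control_carrier_freq = 2 / 381,
                                   true_odds_ratio = 4.59,
                                   missing_rate = 0, n_variants = 1L,
                                   seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_cases >= 1L, n_controls >= 1L,
            control_carrier_freq >= 0, control_carrier_freq <= 1,
            true_odds_ratio > 0, missing_rate >= 0, missing_rate < 1,
            n_variants >= 1L)
  f <- control_carrier_freq; r <- true_odds_ratio
  p_case <- r * f / (1 - f + r * f)
  if (p_case >= 1) {
    stop("implied case carrier probability is not below 1", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 control_carrier_freq = f, true_odds_ratio = r,
                 case_carrier_prob = p_case,
                 missing_rate = missing_rate,
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed)),
            class = "replication_sim_config")
}

#' Simulate a replication genotype tally table
#'
#' Draws, per variant, the number of successfully genotyped subjects in each
#' group (binomial with success probability `1 - missing_rate`) and the
#' carrier counts among them (binomial at the group carrier probability),
#' and emits the long tally table consumed by [associate_all()] together
#' with the truth parameters.
#'
#' @param cfg A [replication_sim_config()].
#' @return Object of class `replication_sim`: list with `tallies` (long data
#'   frame: `variant_id`, `group`, `genotype`, `count`), `truth` (list of
#'   the generating parameters), and `config`.
#' @export
simulate_replication <- function(cfg) {
  stopifnot(inherits(cfg, "replication_sim_config"))
  with_seed(cfg$seed, {
    nv <- cfg$n_variants
    typed_cases <- stats::rbinom(nv, cfg$n_cases, 1 - cfg$missing_rate)
    typed_controls <- stats::rbinom(nv, cfg$n_controls, 1 - cfg$missing_rate)
    case_car <- stats::rbinom(nv, typed_cases, cfg$case_carrier_prob)
    control_car <- stats::rbinom(nv, typed_controls, cfg$control_carrier_freq)
    vid <- sprintf("V%05d", seq_len(nv))
    tallies <- data.frame(
      variant_id = rep(vid, each = 4L),
      group = rep(c("case", "case", "control", "control"), nv),
      genotype = rep(c("het", "hom_ref"), 2L * nv),
      count = as.integer(rbind(case_car, typed_cases - case_car,
                               control_car, typed_controls - control_car)),
      stringsAsFactors = FALSE
    )
    structure(list(
      tallies = tallies,
      truth = list(control_carrier_freq = cfg$control_carrier_freq,
                   case_carrier_prob = cfg$case_carrier_prob,
                   true_odds_ratio = cfg$true_odds_ratio,
                   missing_rate = cfg$missing_rate),
      config = cfg
    ), class = "replication_sim")
  })
}

#' @export
print.replication_sim <- function(x, ...) {
  cat("Synthetic replication cohort: ", x$config$n_variants, " variant(s), ",
      x$config$n_cases, " cases / ", x$config$n_controls, " controls, true OR ",
      x$truth$true_odds_ratio, "\n", sep = "")
  invisible(x)
}
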
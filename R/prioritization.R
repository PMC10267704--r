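#' Read-support quality thresholds
#'
#' A call is high-confidence when it has at least `min_total_reads` total
#' reads, at least `min_variant_reads` reads supporting the alternate allele,
#' and a variant-read fraction of at least `min_variant_fraction`. The
#' defaults (10 reads, 5 variant reads, 20 percent) are the standard
#' post-calling confidence cut for short-read germline data.
#'
#' @param min_total_reads Minimum total read depth (default 10).
#' @param min_variant_reads Minimum alternate-supporting reads (default 5).
#' @param min_variant_fraction Minimum alternate-read fraction in (0, 1]
#'   (default 0.20).
#' @return Object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_total_reads = 10L, min_variant_reads = 5L,
                               min_variant_fraction = 0.20) {
  stopifnot(min_total_reads > 0, min_variant_reads > 0,
            min_variant_fraction > 0, min_variant_fraction <= 1)
  structure(list(min_total_reads = as.integer(min_total_reads),
                 min_variant_reads = as.integer(min_variant_reads),
                 min_variant_fraction = min_variant_fraction),
            class = "quality_thresholds")
}

#' Population rarity thresholds
#'
#' A variant is retained as rare when every reference-panel allele frequency
#' that is *present* in its annotation is at most `max_maf` (the filter
#' removes variants with MAF strictly greater than the threshold; absent
#' frequencies pass — absence from a panel is evidence of rarity, not a
#' frequency of zero) and, when `require_inhouse_absent`, the variant is not
#' flagged as present in the in-house exome database.
#'
#' @param max_maf Maximum minor allele frequency (default 0.001).
#' @param require_inhouse_absent Require absence from the in-house database
#'   (default TRUE).
#' @return Object of class `rarity_thresholds`.
#' @export
rarity_thresholds <- function(max_maf = 0.001, require_inhouse_absent = TRUE) {
  stopifnot(max_maf >= 0, max_maf <= 1)
  structure(list(max_maf = max_maf,
                 require_inhouse_absent = isTRUE(require_inhouse_absent)),
            class = "rarity_thresholds")
}

#' Conservation threshold for missense variants
#'
#' Missense variants count as protein-altering only at highly conserved
#' positions, phyloP at least `min_phylop` (default 3.0). Truncating classes
#' (nonsense, frameshift, canonical splice) are protein-altering regardless
#' of conservation.
#'
#' @param min_phylop Minimum phyloP score for missense retention (default 3.0).
#' @return Object of class `conservation_threshold`.
#' @export
conservation_threshold <- function(min_phylop = 3.0) {
  stopifnot(is.finite(min_phylop))
  structure(list(min_phylop = min_phylop), class = "conservation_threshold")
}

#' High-confidence call predicate
#'
#' @param calls Data frame of calls (`genotype`, `total_reads`,
#'   `variant_reads`), as returned by [read_vcf()].
#' @param thresholds A [quality_thresholds()] object.
#' @return Logical vector, one element per call.
#' @export
is_high_confidence <- function(calls, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  bad <- calls$total_reads == 0L & calls$genotype != "missing"
  if (any(bad)) {
    stop("call with zero total reads but non-missing genotype (",
         sum(bad), " record(s))", call. = FALSE)
  }
  calls$total_reads >= thresholds$min_total_reads &
    calls$variant_reads >= thresholds$min_variant_reads &
    calls$variant_reads >= thresholds$min_variant_fraction * calls$total_reads
}

#' Protein-altering predicate
#'
#' Truncating consequences (nonsense, frameshift, canonical splice) are
#' always protein-altering; missense variants only when their phyloP meets
#' the conservation threshold; synonymous and other consequences never.
#' Missense variants with no phyloP annotation are excluded by default
#' (conservative) — set `missense_missing_phylop = "include"` to keep them.
#'
#' @param variants Annotated variant data frame (`consequence`, `phylop`).
#' @param conservation A [conservation_threshold()] object.
#' @param missense_missing_phylop `"exclude"` (default) or `"include"`.
#' @return Logical vector, one element per variant.
#' @export
is_protein_altering <- function(variants,
                                conservation = conservation_threshold(),
                                missense_missing_phylop = c("exclude", "include")) {
  stopifnot(inherits(conservation, "conservation_threshold"))
  missense_missing_phylop <- match.arg(missense_missing_phylop)
  csq <- variants$consequence
  truncating <- csq %in% c("nonsense", "frameshift", "canonical_splice")
  mis <- csq == "missense"
  phy_ok <- !is.na(variants$phylop) & variants$phylop >= conservation$min_phylop
  if (missense_missing_phylop == "include") {
    phy_ok <- phy_ok | is.na(variants$phylop)
  }
  truncating | (mis & phy_ok)
}

#' Rarity predicate
#'
#' @param variants Annotated variant data frame (frequency columns
#'   `maf_dbsnp`, `maf_esp`, `maf_exac`, `maf_1kg`, flag `inhouse_present`).
#' @param thresholds A [rarity_thresholds()] object.
#' @return Logical vector, one element per variant.
#' @export
is_rare <- function(variants, thresholds = rarity_thresholds()) {
  stopifnot(inherits(thresholds, "rarity_thresholds"))
  ok <- rep(TRUE, nrow(variants))
  for (col in c("maf_dbsnp", "maf_esp", "maf_exac", "maf_1kg")) {
    f <- variants[[col]]
    ok <- ok & (is.na(f) | f <= thresholds$max_maf)
  }
  if (thresholds$require_inhouse_absent) {
    inh <- variants$inhouse_present
    ok <- ok & !(!is.na(inh) & inh)
  }
  ok
}

#' Family-sharing predicate
#'
#' A variant is shared in a family when *every* index patient of that family
#' carries at least one alternate allele there with a high-confidence call.
#' An index patient with no call record, a missing genotype, or a
#' low-confidence call counts as a non-carrier (absence of evidence is not
#' evidence of sharing). The variant passes the filter when sharing holds in
#' at least one family (or in the specific `family`, if given).
#'
#' @param variant_id Character vector of variant ids to evaluate.
#' @param calls Call data frame (as from [read_vcf()]).
#' @param pedigree Pedigree data frame (as from [read_pedigree()]).
#' @param quality [quality_thresholds()] applied to carrier calls.
#' @param family Optional single family id restricting the check.
#' @return Named logical vector over `variant_id`.
#' @export
shared_in_family <- function(variant_id, calls, pedigree,
                             quality = quality_thresholds(), family = NULL) {
  pedigree <- validate_pedigree(pedigree)
  idx <- pedigree[pedigree$index, , drop = FALSE]
  if (!is.null(family)) {
    idx <- idx[idx$family_id %in% family, , drop = FALSE]
    if (nrow(idx) == 0L) stop("unknown family: ", family, call. = FALSE)
  }
  need <- table(idx$family_id)

  keep <- calls$variant_id %in% variant_id &
    calls$sample %in% idx$sample_id &
    calls$genotype %in% c("het", "hom_alt")
  el <- calls[keep, , drop = FALSE]
  el <- el[is_high_confidence(el), , drop = FALSE]
  el$family_id <- idx$family_id[match(el$sample, idx$sample_id)]
  el <- unique(el[, c("variant_id", "sample", "family_id")])

  cnt <- table(factor(el$variant_id, levels = variant_id),
               factor(el$family_id, levels = names(need)))
  full <- sweep(cnt, 2L, as.integer(need), `>=`)
  out <- apply(full, 1L, any)
  names(out) <- variant_id
  out
}

#' Candidate-gene category of prioritized variants
#'
#' Assigns each variant the first matching category: `gwas` if its gene lies
#' in the IBD GWAS panel, else `pid` (primary immunodeficiency genes), else
#' `pathway` (IBD-implicated pathway genes), else `novel` if the variant is
#' protein-altering, else `none`.
#'
#' @param variants Annotated variant data frame.
#' @param panels A [gene_panels()] object.
#' @param protein_altering Logical vector per variant; computed via
#'   [is_protein_altering()] with default thresholds when omitted.
#' @return Character vector in `c("gwas","pid","pathway","novel","none")`.
#' @export
assign_candidate_category <- function(variants, panels,
                                      protein_altering = NULL) {
  stopifnot(inherits(panels, "gene_panels"))
  if (is.null(protein_altering)) {
    protein_altering <- is_protein_altering(variants)
  }
  g <- toupper(variants$gene)
  out <- rep("none", nrow(variants))
  out[protein_altering] <- "novel"
  out[g %in% panels$pathway] <- "pathway"
  out[g %in% panels$pid] <- "pid"
  out[g %in% panels$gwas] <- "gwas"
  out
}

#' Run the prioritization cascade
#'
#' Applies the staged variant filters in order and records the surviving
#' count after each stage:
#' \enumerate{
#'   \item coding/canonical-splice consequence with at least one
#'     high-confidence carrier call (`coding_quality`);
#'   \item non-synonymous or canonical-splice consequence (`nonsynonymous`);
#'   \item shared by all index patients of at least one family *and*
#'     protein-altering (`family_shared_protein_altering`);
#'   \item rare in all annotated reference panels and absent in-house
#'     (`rare`);
#'   \item candidate-gene category other than `none` (`candidate_gene`);
#'   \item optionally, membership of an externally supplied visual-review
#'     pass list (`pass_list`) and of an assay-capacity cap list
#'     (`cap_list`).
#' }
#' Filters only remove variants, so stage counts are monotone non-increasing,
#' each stage is idempotent, and the sharing and rarity stages commute.
#'
#' @param variants Annotated variant data frame (as from [read_vcf()] or
#'   [simulate_families()]).
#' @param calls Call data frame.
#' @param pedigree Pedigree data frame.
#' @param panels A [gene_panels()] object.
#' @param quality,rarity,conservation Threshold objects.
#' @param missense_missing_phylop Passed to [is_protein_altering()].
#' @param pass_list,cap_list Optional character vectors of variant ids; when
#'   given, applied as final restriction stages.
#' @return Object of class `cascade_report`: list with `stages` (data frame
#'   of stage name and surviving count, first row the unfiltered input),
#'   `variants` (surviving annotated variants with a `category` column),
#'   `exclusions` (data frame `variant_id`, `stage` naming the stage at which
#'   each removed variant dropped out), and `thresholds`.
#' @export
run_cascade <- function(variants, calls, pedigree, panels,
                        quality = quality_thresholds(),
                        rarity = rarity_thresholds(),
                        conservation = conservation_threshold(),
                        missense_missing_phylop = c("exclude", "include"),
                        pass_list = NULL, cap_list = NULL) {
  missense_missing_phylop <- match.arg(missense_missing_phylop)
  pedigree <- validate_pedigree(pedigree)
  stopifnot(inherits(panels, "gene_panels"))

  stages <- character(); counts <- integer()
  exclusions <- list()
  note <- function(stage, n) {
    stages <<- c(stages, stage); counts <<- c(counts, n)
  }
  cur <- variants
  note("all", nrow(cur))
  apply_stage <- function(stage, keep) {
    dropped <- cur$variant_id[!keep]
    if (length(dropped)) {
      exclusions[[stage]] <<- data.frame(variant_id = dropped, stage = stage,
                                         stringsAsFactors = FALSE)
    }
    cur <<- cur[keep, , drop = FALSE]
    note(stage, nrow(cur))
  }

  if (nrow(cur) > 0L) {
    # stage 1: coding/canonical-splice region + read-support quality
    coding <- cur$consequence %in% setdiff(consequence_classes(), "other")
    hc <- calls[is_high_confidence(calls, quality) &
                  calls$genotype %in% c("het", "hom_alt"), "variant_id"]
    apply_stage("coding_quality", coding & cur$variant_id %in% hc)

    # stage 2: non-synonymous / canonical splice
    apply_stage("nonsynonymous",
                cur$consequence %in% c("missense", "nonsense", "frameshift",
                                       "canonical_splice"))

    # stage 3: family-shared + protein-altering
    pa <- is_protein_altering(cur, conservation, missense_missing_phylop)
    sh <- shared_in_family(cur$variant_id, calls, pedigree, quality)
    apply_stage("family_shared_protein_altering", pa & unname(sh))

    # stage 4: rarity
    apply_stage("rare", is_rare(cur, rarity))

    # stage 5: candidate-gene category
    cur$category <- assign_candidate_category(
      cur, panels, is_protein_altering(cur, conservation, missense_missing_phylop))
    apply_stage("candidate_gene", cur$category != "none")

    if (!is.null(pass_list)) {
      apply_stage("pass_list", cur$variant_id %in% pass_list)
    }
    if (!is.null(cap_list)) {
      apply_stage("cap_list", cur$variant_id %in% cap_list)
    }
  } else {
    for (s in c("coding_quality", "nonsynonymous",
                "family_shared_protein_altering", "rare", "candidate_gene")) {
      note(s, 0L)
    }
    cur$category <- character(0L)
  }

  exclusions <- if (length(exclusions)) {
    do.call(rbind, c(exclusions, list(make.row.names = FALSE)))
  } else {
    data.frame(variant_id = character(), stage = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    stages = data.frame(stage = stages, n = counts, stringsAsFactors = FALSE),
    variants = cur,
    exclusions = exclusions,
    thresholds = list(quality = quality, rarity = rarity,
                      conservation = conservation)
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Variant prioritization cascade\n")
  w <- max(nchar(x$stages$stage))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-*s %s\n", w, x$stages$stage[i],
                format(x$stages$n[i], big.mark = ",")))
  }
  if (nrow(x$variants) > 0L && "category" %in% names(x$variants)) {
    tab <- table(x$variants$category)
    cat("Final set by candidate category: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cascade_report <- function(object, ...) object$stages

#' Write a cascade report to disk
#'
#' Writes the per-stage surviving counts as TSV and, optionally, the
#' variant-level detail (surviving variants with category, plus per-variant
#' exclusion stage) as JSON.
#'
#' @param report A `cascade_report` from [run_cascade()].
#' @param tsv_path Output path for the stage-count TSV.
#' @param json_path Optional output path for the JSON detail file.
#' @return Invisibly, `tsv_path`.
#' @export
write_cascade_report <- function(report, tsv_path, json_path = NULL) {
  stopifnot(inherits(report, "cascade_report"))
  write_tsv(report$stages, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(stages = report$stages, variants = report$variants,
           exclusions = report$exclusions),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(tsv_path)
}
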
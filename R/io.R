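#' Default INFO keys for variant annotations
#'
#' Maps the annotation fields the prioritization cascade consumes onto the
#' VCF INFO keys they are stored under. Override individual entries via the
#' `annotation_keys` argument of [read_vcf()] when ingesting VCFs annotated
#' with a different convention.
#'
#' @return Named list of INFO key names: `gene`, `consequence`, `phylop`,
#'   `maf_dbsnp`, `maf_esp`, `maf_exac`, `maf_1kg`, `inhouse`.
#' @export
default_annotation_keys <- function() {
  list(gene = "GENE", consequence = "CSQ", phylop = "PHYLOP",
       maf_dbsnp = "AF_DBSNP", maf_esp = "AF_ESP", maf_exac = "AF_EXAC",
       maf_1kg = "AF_1KG", inhouse = "INHOUSE")
}

#' Consequence classes recognised by the cascade
#' @return Character vector of the consequence vocabulary.
#' @export
consequence_classes <- function() {
  c("missense", "nonsense", "frameshift", "canonical_splice",
    "synonymous", "other")
}

genotype_classes <- function() c("hom_ref", "het", "hom_alt", "missing")

# Pull one key out of raw INFO strings. Supports both `KEY=value` pairs and
# bare presence flags (which yield "1"). Returns NA where the key is absent.
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "(?:=([^;]*))?(?:;|$)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) {
    if (length(g) == 0L) return(NA_character_)
    if (length(g) >= 2L && nzchar(g[2L])) g[2L] else "1"
  }, character(1L))
}

# Per-alt slice of a comma-separated (Number=A) annotation value.
alt_slice <- function(values, alt_index) {
  parts <- strsplit(values, ",", fixed = TRUE)
  mapply(function(p, k) {
    if (length(p) == 0L || all(is.na(p))) NA_character_
    else if (length(p) >= k) p[k] else p[1L]
  }, parts, alt_index, USE.NAMES = FALSE)
}

num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c(".", ""), NA, x)))

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("1", "true", "t", "yes", "y")
}

# Light structural validation before handing the file to the parser, so
# malformed input is reported with a line number.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) {
    stop("malformed VCF header in '", path,
         "': no #CHROM column line found", call. = FALSE)
  }
  ncol_hdr <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  if (ncol_hdr < 10L) {
    stop("malformed VCF header at line ", hdr, " of '", path,
         "': need FORMAT plus at least one sample column", call. = FALSE)
  }
  body <- which(seq_along(lines) > hdr & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != ncol_hdr) {
      stop("malformed VCF record at line ", i, " of '", path, "': expected ",
           ncol_hdr, " fields, found ", length(f), call. = FALSE)
    }
    if (!grepl("(^|:)GT($|:)", f[9L])) {
      stop("VCF format error at line ", i, " of '", path,
           "': FORMAT lacks the GT field", call. = FALSE)
    }
  }
  invisible(length(body))
}

# Genotype class of a GT string with respect to alternate allele index k.
gt_class <- function(gt, k) {
  al <- strsplit(gt, "[/|]")
  mapply(function(a, kk) {
    if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return("missing")
    n <- sum(a == as.character(kk))
    if (n == 0L) "hom_ref" else if (n == 1L) "het" else "hom_alt"
  }, al, k, USE.NAMES = FALSE)
}

#' Read an annotated multi-sample VCF
#'
#' Parses a VCF 4.x file into the two tables the cascade consumes: a
#' site-by-allele annotation table and a per-sample call table with read
#' support. Multi-allelic sites are decomposed into one record per alternate
#' allele; the genotype of a sample with respect to allele k is `het` if
#' exactly one of its alleles is k, `hom_alt` if both are, `hom_ref` if
#' neither, and `missing` for no-calls (phased and unphased separators are
#' treated identically). Annotation values are read from INFO; absent values
#' stay `NA` (absent-from-panel and frequency zero are distinct states for
#' the rarity filter).
#'
#' @param path Path to a VCF file with per-sample GT and DP and/or AD fields.
#' @param annotation_keys Named list mapping annotation fields to INFO keys,
#'   see [default_annotation_keys()].
#' @return List with elements
#'   \describe{
#'     \item{variants}{data frame: `variant_id`, `chrom`, `pos`, `ref`,
#'       `alt`, `gene`, `consequence`, `phylop`, `maf_dbsnp`, `maf_esp`,
#'       `maf_exac`, `maf_1kg`, `inhouse_present`.}
#'     \item{calls}{data frame: `variant_id`, `sample`, `genotype`,
#'       `total_reads`, `variant_reads`.}
#'   }
#' @export
read_vcf <- function(path, annotation_keys = default_annotation_keys()) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(list(variants = empty_variants(), calls = empty_calls()))
  }
  samples <- colnames(vcf@gt)[-1L]

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  ridx <- rep(seq_len(nrow(fix)), n_alt)
  aidx <- sequence(n_alt)

  info <- fix[, "INFO"]
  ann <- function(field, numeric = FALSE) {
    v <- alt_slice(info_field(info, annotation_keys[[field]])[ridx], aidx)
    if (numeric) num_or_na(v) else ifelse(v %in% c(".", ""), NA, v)
  }

  variants <- data.frame(
    chrom = fix[ridx, "CHROM"],
    pos = as.integer(fix[ridx, "POS"]),
    ref = toupper(fix[ridx, "REF"]),
    alt = toupper(unlist(alt_list)),
    gene = toupper(ann("gene")),
    consequence = ann("consequence"),
    phylop = ann("phylop", numeric = TRUE),
    maf_dbsnp = ann("maf_dbsnp", numeric = TRUE),
    maf_esp = ann("maf_esp", numeric = TRUE),
    maf_exac = ann("maf_exac", numeric = TRUE),
    maf_1kg = ann("maf_1kg", numeric = TRUE),
    inhouse_present = as_flag(ann("inhouse")) & !is.na(ann("inhouse")),
    stringsAsFactors = FALSE
  )
  variants$consequence[is.na(variants$consequence)] <- "other"
  bad_csq <- !variants$consequence %in% consequence_classes()
  if (any(bad_csq)) {
    stop("unknown consequence class in '", path, "': ",
         paste(unique(variants$consequence[bad_csq]), collapse = ", "),
         call. = FALSE)
  }
  variants$variant_id <- format_variant_key(variants)
  validate_variant_key(variants)
  variants <- variants[, c("variant_id", setdiff(names(variants), "variant_id"))]

  gtm <- vcfR::extract.gt(vcf, "GT")
  dpm <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  adm <- vcfR::extract.gt(vcf, "AD")

  nrec <- length(ridx)
  calls <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    gt <- gtm[ridx, s]
    ad <- strsplit(ifelse(is.na(adm[ridx, s]), "", adm[ridx, s]), ",", fixed = TRUE)
    vr <- mapply(function(p, k) {
      v <- suppressWarnings(as.integer(p))
      if (length(v) >= k + 1L && !is.na(v[k + 1L])) v[k + 1L] else 0L
    }, ad, aidx, USE.NAMES = FALSE)
    tot <- dpm[ridx, s]
    ad_sum <- vapply(ad, function(p) {
      v <- suppressWarnings(as.integer(p))
      if (length(v) == 0L || all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
    }, integer(1L))
    tot <- ifelse(is.na(tot), ad_sum, tot)
    tot[is.na(tot)] <- 0L
    calls[[s]] <- data.frame(
      variant_id = variants$variant_id,
      sample = samples[s],
      genotype = gt_class(gt, aidx),
      total_reads = as.integer(tot),
      variant_reads = as.integer(vr),
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  if (any(calls$variant_reads > calls$total_reads)) {
    stop("inconsistent read counts in '", path,
         "': variant reads exceed total reads", call. = FALSE)
  }
  list(variants = variants, calls = calls)
}

empty_variants <- function() {
  data.frame(variant_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             consequence = character(), phylop = numeric(),
             maf_dbsnp = numeric(), maf_esp = numeric(), maf_exac = numeric(),
             maf_1kg = numeric(), inhouse_present = logical(),
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(variant_id = character(), sample = character(),
             genotype = character(), total_reads = integer(),
             variant_reads = integer(), stringsAsFactors = FALSE)
}

#' Read a pedigree table
#'
#' Reads the tab-separated family table: one row per sequenced member with
#' columns `family_id`, `sample_id`, `affected`, `index` and optionally
#' `kinship`. `index` flags the index patients (probands) whose shared
#' variants drive the family filter.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `family_id`, `sample_id`, `affected`
#'   (logical), `index` (logical), `kinship` (character, `NA` if absent).
#' @export
read_pedigree <- function(path) {
  d <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("cannot read pedigree '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  validate_pedigree(d, path)
}

validate_pedigree <- function(d, what = "pedigree") {
  need <- c("family_id", "sample_id", "affected", "index")
  if (!all(need %in% names(d))) {
    stop("pedigree '", what, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0L) stop("pedigree '", what, "' is empty", call. = FALSE)
  d$affected <- as_flag(d$affected)
  d$index <- as_flag(d$index)
  if (!"kinship" %in% names(d)) d$kinship <- NA_character_
  dup <- duplicated(d$sample_id)
  if (any(dup)) {
    stop("duplicate sample id in pedigree: ",
         paste(unique(d$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  no_index <- setdiff(unique(d$family_id), unique(d$family_id[d$index]))
  if (length(no_index)) {
    stop("family without an index patient: ",
         paste(no_index, collapse = ", "), call. = FALSE)
  }
  d[, c("family_id", "sample_id", "affected", "index", "kinship")]
}

#' Read a gene panel
#'
#' Reads a plain-text gene panel: one symbol per line, `#` comments allowed.
#' Symbols are upper-cased and deduplicated.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique uppercase gene symbols.
#' @export
read_gene_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- unique(toupper(lines[nzchar(lines)]))
  if (length(genes) == 0L) {
    stop("gene panel '", path, "' contains no symbols", call. = FALSE)
  }
  genes
}

#' Bundle candidate-gene panels
#'
#' The cascade categorizes surviving variants against three panels: genes at
#' known IBD GWAS susceptibility loci, primary immunodeficiency (PID) genes,
#' and genes of IBD-implicated pathways (innate immune system, immune system,
#' neutrophil degranulation).
#'
#' @param gwas,pid,pathway Character vectors of gene symbols (or paths are
#'   accepted by [read_gene_panels()]).
#' @return Object of class `gene_panels`: list with elements `gwas`, `pid`,
#'   `pathway`.
#' @export
gene_panels <- function(gwas, pid, pathway) {
  chk <- function(x, nm) {
    x <- unique(toupper(x))
    if (length(x) == 0L || any(!nzchar(x))) {
      stop("panel '", nm, "' must be a non-empty set of symbols", call. = FALSE)
    }
    x
  }
  structure(list(gwas = chk(gwas, "gwas"), pid = chk(pid, "pid"),
                 pathway = chk(pathway, "pathway")),
            class = "gene_panels")
}

#' Read the three candidate-gene panels from files
#' @param gwas_path,pid_path,pathway_path Paths to plain-text panel files.
#' @return A [gene_panels()] object.
#' @export
read_gene_panels <- function(gwas_path, pid_path, pathway_path) {
  gene_panels(read_gene_panel(gwas_path), read_gene_panel(pid_path),
              read_gene_panel(pathway_path))
}

#' Read a replication genotype tally table
#'
#' Reads the per-variant genotype tallies of a case-control replication
#' cohort: columns `variant_id`, `group` (`case`/`control`), `genotype`
#' (`hom_ref`, `het`, `hom_alt`, `missing`), `count`, and optionally `gene`
#' and `rsid`. Per-variant denominators may differ (genotyping missingness);
#' counts are taken as given and never renormalized.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_replication_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("variant_id", "group", "genotype", "count")
  if (!all(need %in% names(d))) {
    stop("replication table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d$group <- tolower(d$group)
  if (!all(d$group %in% c("case", "control"))) {
    stop("replication table group must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(d$genotype %in% genotype_classes())) {
    stop("unknown genotype class in replication table: ",
         paste(setdiff(unique(d$genotype), genotype_classes()), collapse = ", "),
         call. = FALSE)
  }
  d$count <- as.integer(d$count)
  if (any(is.na(d$count) | d$count < 0L)) {
    stop("replication table counts must be non-negative integers", call. = FALSE)
  }
  if (!"gene" %in% names(d)) d$gene <- NA_character_
  if (!"rsid" %in% names(d)) d$rsid <- NA_character_
  d
}

#' Read a clinical characteristics table
#'
#' Reads per-patient clinical records coded with the Montreal classification
#' of Crohn's disease: `location` is a `+`-separated combination over
#' L1 (terminal ileum), L2 (colon), L3 (ileocolon) with L4 (upper GI) only as
#' a modifier; `behavior` is B1 (non-stricturing, non-penetrating),
#' B2 (stricturing) or B3 (penetrating). `duration` supports the
#' left-censored value `"<1"` (stored as 0.5 with `duration_censored` set).
#'
#' @param path Path to the TSV file with columns `patient_id`, `age`, `sex`,
#'   `location`, `behavior` and optionally `family_id`, `kinship`,
#'   `duration`, `pelvic_disease`, `abdominal_surgery`.
#' @return Validated data frame; `location` is kept as the coded string and
#'   expanded on demand by [summarize_cohort()].
#' @export
read_clinical_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("patient_id", "age", "sex", "location", "behavior")
  if (!all(need %in% names(d))) {
    stop("clinical table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) == 0L) stop("clinical table '", path, "' is empty", call. = FALSE)
  d$sex <- tolower(d$sex)
  if (!all(d$sex %in% c("male", "female"))) {
    stop("sex must be male/female", call. = FALSE)
  }
  loc <- strsplit(d$location, "+", fixed = TRUE)
  codes <- unique(unlist(loc))
  if (!all(codes %in% c("L1", "L2", "L3", "L4"))) {
    stop("unknown disease location code: ",
         paste(setdiff(codes, c("L1", "L2", "L3", "L4")), collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(loc, function(l) length(l) == 0L || identical(l, "L4"), logical(1L)))) {
    stop("location must be non-empty; L4 is a modifier and cannot stand alone",
         call. = FALSE)
  }
  if (!all(d$behavior %in% c("B1", "B2", "B3"))) {
    stop("behavior must be one of B1, B2, B3", call. = FALSE)
  }
  if ("duration" %in% names(d)) {
    d$duration_censored <- trimws(as.character(d$duration)) == "<1"
    d$duration_years <- ifelse(d$duration_censored, 0.5,
                               suppressWarnings(as.numeric(d$duration)))
  }
  for (col in c("pelvic_disease", "abdominal_surgery")) {
    if (col %in% names(d)) d[[col]] <- as_flag(d[[col]])
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
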
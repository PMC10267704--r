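# Shared builders for small in-code fixtures.

# A minimal annotated two-sample VCF, returned as a temp file path.
write_mini_vcf <- function(records,
                           samples = c("S1", "S2"),
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=PHYLOP,Number=A,Type=Float,Description=\"p\">",
    "##INFO=<ID=AF_EXAC,Number=A,Type=Float,Description=\"f\">",
    "##INFO=<ID=INHOUSE,Number=A,Type=Integer,Description=\"i\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  path <- file.path(dir, "mini.vcf")
  writeLines(c(header, records), path)
  path
}

# One variant row in the annotation-table shape used across the package.
variant_row <- function(variant_id = "chr1:100A>T", chrom = "chr1",
                        pos = 100L, ref = "A", alt = "T", gene = "GENE1",
                        consequence = "missense", phylop = 5,
                        maf_dbsnp = NA_real_, maf_esp = NA_real_,
                        maf_exac = NA_real_, maf_1kg = NA_real_,
                        inhouse_present = FALSE) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, gene = gene, consequence = consequence,
             phylop = phylop, maf_dbsnp = maf_dbsnp, maf_esp = maf_esp,
             maf_exac = maf_exac, maf_1kg = maf_1kg,
             inhouse_present = inhouse_present, stringsAsFactors = FALSE)
}

call_row <- function(variant_id, sample, genotype = "het",
                     total_reads = 30L, variant_reads = 15L) {
  data.frame(variant_id = variant_id, sample = sample, genotype = genotype,
             total_reads = as.integer(total_reads),
             variant_reads = as.integer(variant_reads),
             stringsAsFactors = FALSE)
}

two_family_pedigree <- function() {
  data.frame(
    family_id = c("FA", "FA", "FB", "FB"),
    sample_id = c("FA-1", "FA-2", "FB-1", "FB-2"),
    affected = TRUE, index = TRUE, kinship = "siblings",
    stringsAsFactors = FALSE
  )
}

test_panels <- function() {
  gene_panels(gwas = c("NOD2", "TNFSF15"), pid = c("BTK", "WAS"),
              pathway = c("SIRPB1", "TLR4"))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "famrvar")
}

# Independent enumeration oracle for the two-sided Fisher p-value: iterate
# every table with the observed margins via log-binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  if (r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, r1 - c2):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(c2, r1 - support) - lchoose(N, r1)
  p <- exp(logp)
  p_obs <- exp(lchoose(c1, a) + lchoose(c2, r1 - a) - lchoose(N, r1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
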
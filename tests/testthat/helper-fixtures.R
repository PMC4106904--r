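# small deterministic fixtures built in code

# panel from haplotype strings like c("0101", "1010", ...)
make_panel <- function(rows, pos = NULL, chrom = "1", population = "test") {
  al <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  m <- ncol(al)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = m)
  haplotype_panel(
    al,
    tibble::tibble(id = paste0("s", seq_len(m)), chrom = chrom, pos = as.integer(pos)),
    population = population
  )
}

# minimal phased VCF writer for io tests
write_test_vcf <- function(path, samples, records) {
  # records: list of list(chrom, pos, id, ref, alt, gts = c("0|1", ...))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  for (r in records) {
    lines <- c(lines, paste(
      c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gts),
      collapse = "\t"
    ))
  }
  writeLines(lines, path)
  path
}

# a small panel with strong planted signal for fast end-to-end tests:
# dense spacing so neighbour counts are high at few SNPs
small_scan_config <- function(seed, n_snps = 400, planted = list()) {
  sim_config(
    n_animals = 60L, n_snps = n_snps, mean_spacing_bp = 2000L,
    n_founders = 4L, recomb_rate_per_bp = 7.5e-6, maf_floor = 0.15,
    seed = seed, planted = planted
  )
}
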
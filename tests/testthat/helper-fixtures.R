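# In-code text fixtures written to temp files at test time.

write_pheno_fixture <- function(path,
                                df = data.frame(
                                  subject_id = c("s1", "s2", "s3"),
                                  bmi = c(24.1, 31.5, 28.0),
                                  waist = c(80, 102, 95),
                                  age = c(35, 41, 38),
                                  sex = c(0, 1, 1))) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_geno_fixture <- function(path,
                               df = data.frame(
                                 subject_id = c("s1", "s2", "s3", "s4"),
                                 snpA = c(0, 1, 2, 0),
                                 snpB = c(1, 0, 0, 1))) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal VCF: snp1 biallelic with ALT minor, snp2 biallelic with ALT as
# the MAJOR allele (codes must be flipped on load), snp3 multiallelic
# (must be skipped).
write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("3", "185210000", "snp1", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0|0", "1/1", sep = "\t"),
    paste("3", "185220000", "snp2", "G", "A", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "1/1", sep = "\t"),
    paste("3", "185230000", "snp3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}
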
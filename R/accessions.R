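# Loaders for the deposited plasmid sequences. The restriction-modification
# genes analysed by this package are deposited in GenBank as CP020571
# (plasmid pTAYT1_11, carrying taqIIIRM) and CP020572 (plasmid pTAYT1_61,
# carrying taqIIRM). Those records are not redistributed with the package;
# download them once and point these loaders at the files.

TAQ_RM_ACCESSIONS <- data.frame(
  accession = c("CP020571", "CP020572"),
  plasmid = c("pTAYT1_11", "pTAYT1_61"),
  gene = c("taqIIIRM", "taqIIRM"),
  orf_nt = c(3306L, 3318L),
  stringsAsFactors = FALSE
)

.accession_file <- function(accession, dir) {
  if (is.null(dir)) dir <- getOption("thermusRM.accession_dir", NULL)
  cand <- character(0)
  if (!is.null(dir))
    cand <- file.path(dir, paste0(accession, c(".gb", ".gbk", ".genbank", ".fasta", ".fa", ".fna")))
  cand <- c(cand, system.file("extdata", paste0(accession, c(".gb", ".fasta")),
                              package = "thermusRM"))
  cand <- cand[nzchar(cand) & file.exists(cand)]
  if (!length(cand))
    stop("deposited sequence ", accession, " not available locally. ",
         "Download the GenBank record (e.g. from the NCBI nucleotide ",
         "database) and pass its directory via `dir` or ",
         "options(thermusRM.accession_dir = ...). Expected a file named ",
         accession, ".gb or ", accession, ".fasta")
  cand[1]
}

#' Load a deposited restriction-modification gene from a local download
#'
#' Reads a locally stored copy of accession CP020571 (taqIIIRM) or CP020572
#' (taqIIRM), locates the restriction-modification ORF (the CDS whose length
#' matches the gene: 3306 bp for taqIIIRM, 3318 bp for taqIIRM; for plain
#' FASTA downloads of just the gene, the whole record), and returns the gene
#' and its translation.
#'
#' @param accession `"CP020571"` or `"CP020572"`.
#' @param dir Directory holding the downloaded file (default: the
#'   `thermusRM.accession_dir` option, then the package's `extdata`).
#' @return List with `gene` (a `nuc_seq`, the ORF on the coding strand) and
#'   `protein` (a `protein_seq`, stop codon removed).
#' @export
load_taq_rm_gene <- function(accession = c("CP020571", "CP020572"), dir = NULL) {
  accession <- match.arg(accession)
  meta <- TAQ_RM_ACCESSIONS[TAQ_RM_ACCESSIONS$accession == accession, ]
  path <- .accession_file(accession, dir)
  if (grepl("\\.(gb|gbk|genbank)$", path)) {
    gb <- read_genbank(path)
    cds <- gb$cds[gb$cds$end - gb$cds$start == meta$orf_nt, , drop = FALSE]
    if (!nrow(cds))
      stop("no CDS of length ", meta$orf_nt, " bp (", meta$gene, ") found in ", path)
    gene_seq <- substr(gb$seq$seq, cds$start[1] + 1L, cds$end[1])
    if (cds$strand[1] == "-") gene_seq <- revcomp(gene_seq)
  } else {
    recs <- read_fasta_dna(path)
    lens <- vapply(recs, function(r) nchar(r$seq), integer(1))
    i <- which(lens == meta$orf_nt)
    if (!length(i))
      stop("no record of length ", meta$orf_nt, " bp (", meta$gene, ") in ", path,
           "; supply the GenBank flat file or the extracted ORF FASTA")
    gene_seq <- recs[[i[1]]]$seq
  }
  gene <- nuc_seq(gene_seq, id = meta$gene)
  aa <- Biostrings::translate(Biostrings::DNAString(gene$seq), no.init.codon = FALSE)
  aa <- sub("\\*$", "", as.character(aa))
  list(gene = gene,
       protein = protein_seq(aa, id = sub("RM$", "", sub("taq", "Taq", meta$gene))))
}
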
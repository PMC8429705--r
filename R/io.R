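#' Read gene/exon models from a GFF3 file
#'
#' Parses a GFF3 annotation via rtracklayer, keeps `gene` and `exon` features
#' (CDS and other types are ignored) and resolves each exon's `Parent` chain
#' up to its gene, so both the flat dialect (exon -> gene) and the common
#' three-level dialect (exon -> mRNA -> gene) are accepted.
#'
#' @param path GFF3 file (1-based, inclusive coordinates).
#' @return data.frame with columns `seqid`, `type`, `id`, `parent`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  ids <- as.character(df$ID)
  parents <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  type <- as.character(df$type)

  # resolve exon parents through intermediate features (e.g. mRNA) to genes
  parent_of <- stats::setNames(parents, ids)
  type_of <- stats::setNames(type, ids)
  resolve_gene <- function(p) {
    for (step in 1:10) {
      if (is.na(p) || !p %in% names(type_of)) return(p)
      if (type_of[[p]] == "gene") return(p)
      p <- parent_of[[p]]
    }
    p
  }
  keep <- type %in% c("gene", "exon")
  out <- data.frame(
    seqid = as.character(df$seqnames)[keep],
    type = type[keep],
    id = ids[keep],
    parent = vapply(parents[keep], resolve_gene, character(1)),
    start = df$start[keep], end = df$end[keep],
    strand = as.character(df$strand)[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene/exon models as GFF3
#'
#' Emits the module's flat GFF3 dialect: `gene` rows with `ID=`, `exon` rows
#' with `ID=` and `Parent=<gene id>`. Reading the file back with
#' [read_gene_models()] reproduces the input records.
#'
#' @param gene_models data.frame with columns `seqid`, `type`, `id`,
#'   `parent`, `start`, `end`, and optionally `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  gm <- gene_models
  strand <- if ("strand" %in% names(gm)) gm$strand else "+"
  strand[is.na(strand) | strand == "*"] <- "+"
  attrs <- ifelse(gm$type == "gene",
                  paste0("ID=", gm$id),
                  paste0("ID=", gm$id, ";Parent=", gm$parent))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   gm$seqid, "ipsgenome", gm$type,
                   as.integer(gm$start), as.integer(gm$end), strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a per-protein domain annotation table
#'
#' Accepts either the package's three-column TSV (`species`, `protein_id`,
#' `domain_accession`, with a header) or hmmscan `--tblout` output
#' (whitespace-delimited, `#` comment lines; the species must then be given,
#' since tblout files are per-proteome). In the tblout dialect, column 1 is
#' the target domain name, column 2 its accession and column 3 the query
#' protein.
#'
#' @param path input file.
#' @param format `"tsv"` or `"hmmscan_tblout"`.
#' @param species species label to attach (required for tblout input).
#' @return data.frame with columns `species`, `protein_id`,
#'   `domain_accession`.
#' @export
read_domain_annotations <- function(path, format = c("tsv", "hmmscan_tblout"),
                                    species = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    .check(all(c("species", "protein_id", "domain_accession") %in% names(df)),
           "TSV must have columns species, protein_id, domain_accession")
    return(df[, c("species", "protein_id", "domain_accession")])
  }
  .check(!is.null(species), "species is required for hmmscan tblout input")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(species = character(0), protein_id = character(0),
                      domain_accession = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  data.frame(
    species = species,
    protein_id = vapply(fields, `[`, character(1), 3L),
    domain_accession = vapply(fields, function(f) sub("[.]\\d+$", "", f[2L]),
                              character(1)),
    stringsAsFactors = FALSE)
}

#' Read / write a species-by-domain count matrix TSV
#'
#' Dialect: species as rows, first column `species`, optional second column
#' `gene_total`, remaining columns one per domain.
#'
#' @param path input/output TSV.
#' @return `read_count_matrix`: a [domain_count_matrix] (if `gene_total` is
#'   present) or a plain integer matrix.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check(names(df)[1] == "species", "first column must be 'species'")
  has_totals <- "gene_total" %in% names(df)
  dom_cols <- setdiff(names(df), c("species", "gene_total"))
  m <- as.matrix(df[, dom_cols, drop = FALSE])
  rownames(m) <- df$species
  storage.mode(m) <- "integer"
  if (!has_totals) return(m)
  domain_count_matrix(m, stats::setNames(df$gene_total, df$species))
}

#' @param x a [domain_count_matrix] or species-by-domain matrix.
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(x, path) {
  if (inherits(x, "domain_count_matrix")) {
    df <- data.frame(species = x$species, gene_total = x$gene_totals,
                     x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(species = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a k-mer depth histogram (`jellyfish histo` dialect)
#'
#' Two space-separated columns, no header: depth, number of distinct
#' canonical k-mers at that depth.
#'
#' @param path input/output file.
#' @param k the k used to build the histogram (not stored in the file).
#' @return `read_kmer_histogram`: a `kmer_histogram` object.
#' @export
read_kmer_histogram <- function(path, k) {
  df <- utils::read.table(path, col.names = c("depth", "count"))
  kmer_histogram(k = k, depth = df$depth, count = df$count)
}

#' @param hist a `kmer_histogram`.
#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(data.frame(hist$depth, hist$count), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality of `I` (Phred 40): the read
#' simulator has no quality model, the placeholder only satisfies the format.
#'
#' @param reads a DNAStringSet.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path, width = 80L)
  } else {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read/write numeric gene-by-sample matrices as TSV
#'
#' Dialect: genes as rows, header row of sample ids, first column `gene_id`.
#' Values are printed with 6 significant digits.
#'
#' @param path input/output TSV.
#' @return `read_matrix_tsv`: a numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @param m numeric matrix with row and column names.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), signif(m, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detoxification-family domain counts for 12 beetle species
#'
#' The packaged comparison table of eight detoxification / pesticide-
#' resistance Pfam families (ligand-gated ion channels, cytochrome P450s,
#' GST N- and C-terminal domains, ABC transporters, UDP-glucosyl
#' transferases, carboxylesterases, cathepsin propeptide inhibitor I29)
#' across three scolytine bark beetles (Ityp, Dpon, Hham) and nine other
#' coleopterans, as printed in the source genome report. `total_printed` is
#' the table's own "Total numbers" row, kept verbatim for consistency checks.
#'
#' @return data.frame with columns `species`, `guild`, the eight family
#'   counts, and `total_printed`.
#' @examples
#' head(detox_domain_counts())
#' @export
detox_domain_counts <- function() {
  path <- system.file("extdata", "table3_detox_domain_counts.tsv",
                      package = "ipsgenome", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Family columns of [detox_domain_counts()]
#' @return character vector of the eight Pfam family column names.
#' @export
detox_family_columns <- function() {
  c("Lig_chan", "p450", "GST_N", "GST_C", "ABC_tran", "UDPGT",
    "COesterase", "Inhibitor_I29")
}
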
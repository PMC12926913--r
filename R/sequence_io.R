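# Readers and writers for proteomes, gene features, metadata and annotation
# output tables.

#' Read a proteome FASTA
#'
#' @param fasta_source path to an amino-acid FASTA file.
#' @param genome_id genome identifier attached to every record.
#' @param features optional feature mapping from [read_features()]; when
#'   supplied, gene context (contig, gene index, strand, coordinates) is taken
#'   from it, otherwise records get gene indices in FASTA order on a single
#'   unknown contig.
#' @return list of `protein_record`s: `protein_id`, `genome_id`, `sequence`
#'   (uppercased, non-canonical residues mapped to X with a warning),
#'   `contig_id`, `gene_index`, `strand`, `start`, `end`.
#' @export
read_proteome <- function(fasta_source, genome_id, features = NULL) {
  ss <- Biostrings::readAAStringSet(fasta_source)
  if (length(ss) == 0) stop("empty FASTA: ", fasta_source)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s) in ", fasta_source, ": ",
         paste(unique(dup), collapse = ", "))
  records <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    seq <- normalize_aa(as.character(ss[[i]]), id = ids[i])
    if (!nzchar(seq)) stop("empty sequence for protein ", ids[i])
    rec <- list(protein_id = ids[i], genome_id = genome_id, sequence = seq,
                contig_id = "unknown", gene_index = i, strand = "+",
                start = NA_integer_, end = NA_integer_)
    if (!is.null(features)) {
      f <- features[features$protein_id == ids[i], , drop = FALSE]
      if (nrow(f) == 1) {
        rec$contig_id <- f$contig
        rec$gene_index <- f$gene_index
        rec$strand <- f$strand
        rec$start <- f$start
        rec$end <- f$end
      } else {
        warning("protein ", ids[i], " has no feature row; gene context unknown")
      }
    }
    class(rec) <- "protein_record"
    records[[i]] <- rec
  }
  records
}

#' Read gene features from GFF3 or TSV
#'
#' GFF3 input uses CDS rows (attribute `ID` or `locus_tag` must match the
#' FASTA protein ids); TSV input requires columns `protein_id contig
#' gene_index strand start end` (`gene_index` may be `.`/empty, in which case
#' it is recomputed). In both cases `gene_index` is the 1-based rank of the
#' CDS by start coordinate within its contig.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or tab-separated feature table.
#' @param genome_id genome identifier (recorded, not interpreted).
#' @return data.frame: `protein_id`, `contig`, `gene_index`, `strand`,
#'   `start`, `end`.
#' @export
read_features <- function(path, genome_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    df <- read_gff_cds(path)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = ".")
    required <- c("protein_id", "contig", "gene_index", "strand", "start",
                  "end")
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop("feature table ", path, " missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- !is.na(df$start) & !is.na(df$end) & df$end < df$start
  if (any(bad)) stop("feature rows with end < start: ",
                     paste(df$protein_id[bad], collapse = ", "))
  ## gene_index = rank by start within contig
  df$gene_index <- NA_integer_
  for (ct in unique(df$contig)) {
    sel <- which(df$contig == ct)
    df$gene_index[sel] <- rank(df$start[sel], ties.method = "first")
  }
  df[, c("protein_id", "contig", "gene_index", "strand", "start", "end")]
}

# Minimal GFF3 CDS reader (rtracklayer is used when available; the fallback
# parser covers the CDS/ID subset needed here).
read_gff_cds <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    d <- as.data.frame(gr)
    d <- d[d$type == "CDS", , drop = FALSE]
    id <- if ("ID" %in% names(d)) d$ID else d$locus_tag
    return(data.frame(protein_id = as.character(id),
                      contig = as.character(d$seqnames),
                      gene_index = NA_integer_,
                      strand = as.character(d$strand),
                      start = d$start, end = d$end,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, 0L) >= 9]
  parts <- parts[vapply(parts, function(x) x[3] == "CDS", TRUE)]
  if (!length(parts)) stop("no CDS rows in ", path)
  getattr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    if (length(m[[1]]) == 2) m[[1]][2] else NA_character_
  }
  data.frame(
    protein_id = vapply(parts, function(x) {
      id <- getattr(x[9], "ID")
      if (is.na(id)) id <- getattr(x[9], "locus_tag")
      id
    }, ""),
    contig = vapply(parts, `[[`, "", 1),
    gene_index = NA_integer_,
    strand = vapply(parts, `[[`, "", 7),
    start = as.integer(vapply(parts, `[[`, "", 4)),
    end = as.integer(vapply(parts, `[[`, "", 5)),
    stringsAsFactors = FALSE)
}

#' Read a genome metadata table
#'
#' @param path TSV with columns `genome_id`, taxonomy ranks (`phylum`,
#'   `class`, `order`, `family`, `genus`, `species`), `size_bp`, `gc_percent`,
#'   `oxygen_labels` (comma-separated raw source labels), `growth_temp_c`,
#'   `gram`; missing values as `.`.
#' @return data.frame of genome records.
#' @export
read_genome_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".")
  if (!"genome_id" %in% names(df)) stop("metadata must have genome_id column")
  if ("size_bp" %in% names(df) && any(df$size_bp <= 0, na.rm = TRUE))
    stop("size_bp must be positive")
  if ("gc_percent" %in% names(df) &&
      any(df$gc_percent < 0 | df$gc_percent > 100, na.rm = TRUE))
    stop("gc_percent outside [0,100]")
  df
}

#' Write annotation tables for a set of genome complements
#'
#' Emits three TSV files with a header comment naming the registry version:
#' `proteins.tsv` (per-protein annotations), `genomes.tsv` (per-genome
#' complement summary) and `complexes.tsv` (complex calls). Missing values
#' are written as `.`.
#'
#' @param complements list of `genome_complement` objects.
#' @param path output directory.
#' @param registry_version version string recorded in the headers.
#' @return named character vector of file paths, invisibly.
#' @export
write_annotations <- function(complements, path,
                              registry_version = "unknown") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  prot <- do.call(rbind, c(lapply(complements, complement_protein_table),
                           list(empty_protein_table())))
  gen <- do.call(rbind, c(lapply(complements, complement_genome_row),
                          list(empty_genome_table())))
  cx <- do.call(rbind, c(lapply(complements, complement_complex_table),
                         list(empty_complex_table())))
  files <- c(proteins = file.path(path, "proteins.tsv"),
             genomes = file.path(path, "genomes.tsv"),
             complexes = file.path(path, "complexes.tsv"))
  hdr <- paste0("# polcensus annotations; registry version ",
                registry_version)
  for (nm in names(files)) {
    df <- switch(nm, proteins = prot, genomes = gen, complexes = cx)
    con <- file(files[[nm]], "w")
    writeLines(hdr, con)
    df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(files)
}

#' Read back a per-protein annotation table
#' @param path `proteins.tsv` written by [write_annotations()].
#' @return data.frame with the same columns and types.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = ".")
  for (col in c("fragment", "polymerase_active", "php_active", "dnaq_active",
                "exo53_active", "clamp_motif", "recA_NT", "imuBC_domain")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
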
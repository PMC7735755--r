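#' @name io_formats
#' @title Readers and writers for the pipeline's external formats
#'
#' @description
#' All genomic intervals are handled as [GenomicRanges::GRanges] internally
#' (1-based, closed intervals, the Bioconductor convention). BED is the only
#' interval dialect read or written: the 0-based half-open BED coordinates
#' are converted at the boundary, and round-tripping a file through
#' [read_bed()] / [write_bed()] reproduces it exactly. Any 1-based interval
#' table must be converted to BED before use. Differential-expression
#' tables, TSS tables, enhancer:gene links and gene sets are
#' tab-separated files with a header line. Motifs are exchanged in MEME
#' minimal format or as a plain probability TSV.
NULL

#' Read a BED file
#'
#' @param path BED file (>= 3 whitespace-separated columns, no header).
#' @param source_id optional dataset identifier stored in
#'   `mcols(x)$source_id`.
#' @return `GRanges`; BED columns 4/5/6 become `bed_name`, `bed_score` and
#'   the strand, any further columns are kept untouched as `bed_extra*`
#'   character columns.
#' @export
read_bed <- function(path, source_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$source_id <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop("malformed BED line ", which(ncols < 3)[1], ": fewer than 3 columns")
  n <- min(ncols)
  tab <- do.call(rbind, lapply(fields, function(f) f[seq_len(n)]))
  chrom <- tab[, 1]
  start0 <- suppressWarnings(as.numeric(tab[, 2]))
  end0 <- suppressWarnings(as.numeric(tab[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("coordinate error at BED line ", bad[1], ": requires 0 <= start < end")
  strand <- if (n >= 6) tab[, 6] else rep(".", length(chrom))
  if (!all(strand %in% c("+", "-", "."))) stop("invalid strand field")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = ifelse(strand == ".", "*", strand))
  if (n >= 4) mcols(gr)$bed_name <- tab[, 4]
  if (n >= 5) mcols(gr)$bed_score <- tab[, 5]
  if (n >= 7) for (j in 7:n) mcols(gr)[[paste0("bed_extra", j - 6)]] <- tab[, j]
  mcols(gr)$source_id <- source_id
  mcols(gr)$n_bed_cols <- n
  gr
}

#' Write a BED file
#'
#' Inverse of [read_bed()]: emits exactly the columns that were read (or,
#' for ranges not produced by [read_bed()], 3 columns plus name/score/strand
#' when present).
#'
#' @param gr `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- if (!is.null(mcols(gr)$n_bed_cols) && length(gr))
    max(mcols(gr)$n_bed_cols) else NA
  name <- if (!is.null(mcols(gr)$bed_name)) mcols(gr)$bed_name else
    rep(".", length(gr))
  score <- if (!is.null(mcols(gr)$bed_score)) mcols(gr)$bed_score else
    rep("0", length(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  if (is.na(n)) {
    n <- if (!all(str == ".")) 6
    else if (!is.null(mcols(gr)$bed_score)) 5
    else if (!is.null(mcols(gr)$bed_name)) 4 else 3
  }
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               format(start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE))
  if (n >= 4) cols <- c(cols, list(name))
  if (n >= 5) cols <- c(cols, list(as.character(score)))
  if (n >= 6) cols <- c(cols, list(str))
  if (n >= 7) for (j in 7:n)
    cols <- c(cols, list(mcols(gr)[[paste0("bed_extra", j - 6)]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' One table per dataset: gene identifier, log2 fold-change and
#' BH-adjusted p-value, column names configurable. Rows without a gene id
#' are dropped (with a message); duplicate gene ids (e.g. multi-mapped
#' array probes) collapse to the row with the smallest adjusted p-value,
#' which is conservative for vote counting.
#'
#' @param path TSV file with a header.
#' @param dataset_id dataset label.
#' @param platform `"microarray"` or `"rnaseq"` (the coverage rule of
#'   [expression_score()] needs it).
#' @param gene_col,lfc_col,p_col column names in the file.
#' @param sign_flip flip the sign of every log2 fold-change (harmonises
#'   knockdown-design tables so that positive means "higher when p63 is
#'   active").
#' @return object of class `de_table`: list with `dataset_id`, `platform`
#'   and a `data` frame (`gene_id`, `log2fc`, `adj_p`).
#' @export
read_de_table <- function(path, dataset_id, platform = c("rnaseq", "microarray"),
                          gene_col = "gene_id", lfc_col = "log2fc",
                          p_col = "adj_p", sign_flip = FALSE) {
  platform <- match.arg(platform)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(gene_col, lfc_col, p_col), names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- data.frame(gene_id = as.character(tab[[gene_col]]),
                   log2fc = as.numeric(tab[[lfc_col]]),
                   adj_p = as.numeric(tab[[p_col]]),
                   stringsAsFactors = FALSE)
  drop <- is.na(df$gene_id) | df$gene_id == ""
  if (any(drop)) {
    message("read_de_table(", dataset_id, "): dropped ", sum(drop),
            " row(s) without gene id")
    df <- df[!drop, , drop = FALSE]
  }
  if (!nrow(df)) stop("no records in DE table: ", path)
  if (any(is.na(df$adj_p)) || any(df$adj_p < 0 | df$adj_p > 1))
    stop("adjusted p-values must lie in [0,1]")
  if (sign_flip) df$log2fc <- -df$log2fc
  df <- df[order(df$adj_p), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(dataset_id = dataset_id, platform = platform, data = df),
            class = "de_table")
}

#' Build a DE table in memory (used by the simulator and in tests)
#' @param dataset_id,platform as in [read_de_table()].
#' @param gene_id,log2fc,adj_p parallel record vectors.
#' @return a `de_table`.
#' @export
de_table <- function(dataset_id, platform, gene_id, log2fc, adj_p) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique within a table")
  structure(list(dataset_id = dataset_id, platform = platform,
                 data = data.frame(gene_id = as.character(gene_id),
                                   log2fc = log2fc, adj_p = adj_p,
                                   stringsAsFactors = FALSE)),
            class = "de_table")
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; only A, C, G, T
#'   and N are accepted.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(readDNAStringSet(path),
                 error = function(e) stop("invalid FASTA: ", conditionMessage(e)))
  seqs <- toupper(as.character(ss))
  letters_seen <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(letters_seen, c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("alphabet error: sequence contains ", paste(bad, collapse = ","),
         " (only A,C,G,T,N allowed)")
  seqs
}

#' Write a genome FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- DNAStringSet(seqs)
  names(ss) <- names(seqs)
  writeXStringSet(ss, path)
  invisible(path)
}

#' Write a motif
#'
#' @param motif a [pwmotif()].
#' @param path output file.
#' @param format `"meme"` (MEME minimal) or `"tsv"` (position, A, C, G, T
#'   probability columns).
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path, format = c("meme", "tsv")) {
  format <- match.arg(format)
  if (!inherits(motif, "pwmotif")) stop("motif must be a pwmotif")
  probs <- motif$probs
  if (format == "meme") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 paste(sprintf("%s %.6f", DNA_BASES, motif$background),
                       collapse = " "),
                 "",
                 paste("MOTIF", motif$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         nrow(probs))), con)
    writeLines(apply(probs, 1, function(r) {
      r <- round(r, 6)
      r[which.max(r)] <- r[which.max(r)] + (1 - sum(r))
      paste(sprintf("%.6f", r), collapse = "  ")
    }), con)
  } else {
    df <- data.frame(pos = seq_len(nrow(probs)), probs, check.names = FALSE)
    write.table(format(df, digits = 8), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a motif written by [write_motif()]
#'
#' @param path motif file.
#' @param format `"meme"` or `"tsv"`; guessed from the first line when
#'   omitted.
#' @param ... passed to [pwmotif()] (e.g. `frac_max`).
#' @return a `pwmotif` (the detection threshold is recomputed).
#' @export
read_motif <- function(path, format = NULL, ...) {
  lines <- readLines(path)
  if (is.null(format))
    format <- if (grepl("^MEME version", lines[1])) "meme" else "tsv"
  if (format == "meme") {
    bg_i <- grep("^Background letter frequencies", lines)
    background <- rep(0.25, 4)
    if (length(bg_i)) {
      toks <- strsplit(trimws(lines[bg_i[1] + 1]), "[ \t]+")[[1]]
      background <- as.numeric(toks[seq(2, 8, by = 2)])
    }
    mot_i <- grep("^MOTIF ", lines)
    if (!length(mot_i)) stop("no MOTIF record in ", path)
    name <- strsplit(lines[mot_i[1]], "[ \t]+")[[1]][2]
    mat_i <- grep("^letter-probability matrix", lines)
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[mat_i[1]]))
    rows <- lines[(mat_i[1] + 1):(mat_i[1] + w)]
    probs <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"), as.numeric))
    pwmotif(probs, background = background, name = name, ...)
  } else {
    tab <- read.delim(path)
    pwmotif(as.matrix(tab[, c("A", "C", "G", "T")]), ...)
  }
}

#' Read a TSS annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `pos` (0-based
#'   bp), `strand`. Multiple TSS per gene are allowed.
#' @return data.frame.
#' @export
read_tss <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "pos", "strand")
  if (length(setdiff(need, names(tab))))
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$pos < 0)) stop("TSS pos must be >= 0")
  tab
}

#' Read an enhancer:gene association table
#'
#' @param path TSV with header columns `chrom`, `start`, `end` (BED-style
#'   0-based half-open), `gene_id`, `elite` (`yes`/`no` or logical).
#' @return `GRanges` with `gene_id` and logical `elite` metadata.
#' @export
read_enhancer_links <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "elite")
  if (length(setdiff(need, names(tab))))
    stop("enhancer table needs columns: ", paste(need, collapse = ", "))
  elite <- if (is.logical(tab$elite)) tab$elite else tab$elite %in% c("yes", "TRUE", "true", "1")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start + 1, tab$end))
  mcols(gr)$gene_id <- tab$gene_id
  mcols(gr)$elite <- elite
  gr
}

#' Read a direction-annotated gene set
#'
#' @param path TSV with header columns `gene_id`, `direction` (`up`/`down`).
#' @return data.frame.
#' @export
read_gene_set <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("gene_id", "direction"), names(tab))))
    stop("gene set needs columns gene_id, direction")
  if (!all(tab$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  tab
}
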
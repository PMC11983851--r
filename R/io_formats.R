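# Coordinate conventions used throughout:
#   BED intervals are 0-based half-open [start, end).
#   SNP positions are 1-based; SNP at position p overlaps [s, e) iff p - 1 is
#   in [s, e), i.e. s < p <= e.
#   Strand is ignored for all overlap operations.

#' Read a BED3+ file of genomic intervals
#'
#' Parses a tab-separated BED file with at least three columns
#' (chrom, start, end). Coordinates are 0-based half-open. Any additional
#' columns are preserved: the fourth is named `name`, further columns keep
#' generic names. Input row order is retained.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and any extra
#'   columns present in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  }
  ncol_out <- max(nf)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad) > 0L) {
    stop("invalid interval on line ", bad[1L],
         ": require 0 <= start < end, got [", start[bad[1L]], ", ",
         end[bad[1L]], ")")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol_out >= 4L) {
    extra_names <- c("name", if (ncol_out > 4L) paste0("V", 5:ncol_out))
    for (k in seq_len(ncol_out - 3L)) {
      out[[extra_names[k]]] <-
        vapply(fields, function(f) if (length(f) >= k + 3L) f[[k + 3L]] else NA_character_,
               character(1))
    }
  }
  out
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` and any extra
#' columns tab-separated without header, preserving row order.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (+ extras).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated file with header. Required columns: `snp_id`,
#' `chrom`, `pos`, `ref`, `alt`, `n`, and either `z` or both `beta` and `se`
#' (in which case `z = beta / se` is computed). Duplicated SNP ids are
#' rejected.
#'
#' @param path Path to a sumstats TSV.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `z`, `n`.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "ref", "alt", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"z" %in% names(df)) {
    if (!all(c("beta", "se") %in% names(df))) {
      stop("sumstats must contain either column 'z' or columns 'beta' and 'se'")
    }
    if (any(df$se == 0)) stop("sumstats has se = 0; z undefined")
    df$z <- df$beta / df$se
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id in sumstats: ",
         df$snp_id[duplicated(df$snp_id)][1L])
  }
  if (any(!is.finite(df$z))) stop("non-finite z in sumstats")
  df[, c("snp_id", "chrom", "pos", "ref", "alt", "z", "n")]
}

#' Write GWAS summary statistics
#' @param sumstats data.frame as returned by [read_sumstats()].
#' @param path Output path.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read chromatin loops (BEDPE + promoter gene)
#'
#' Reads a tab-separated file without header carrying two anchors and the
#' gene whose promoter is captured: `chromA startA endA chromB startB endB
#' gene [cell_type]`. By convention anchor A is the promoter end and anchor B
#' the non-promoter end used for element overlap. Trans (inter-chromosomal)
#' loops are retained and flagged in column `trans`.
#'
#' @param path Path to a BEDPE-like file.
#' @return data.frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `gene`, optional `cell_type`, and logical `trans`.
#' @export
read_loops <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 7L) stop("loop file needs >= 7 columns (6 coordinates + gene)")
  names(df)[1:7] <- c("chromA", "startA", "endA", "chromB", "startB", "endB",
                      "gene")
  if (ncol(df) >= 8L) names(df)[8L] <- "cell_type"
  for (side in c("A", "B")) {
    s <- df[[paste0("start", side)]]
    e <- df[[paste0("end", side)]]
    bad <- which(!is.finite(s) | !is.finite(e) | s >= e | s < 0)
    if (length(bad) > 0L) {
      stop("invalid anchor ", side, " on loop row ", bad[1L],
           ": require 0 <= start < end")
    }
  }
  if (any(is.na(df$gene) | !nzchar(df$gene))) {
    stop("loop row ", which(is.na(df$gene) | !nzchar(df$gene))[1L],
         ": empty promoter gene")
  }
  df$trans <- df$chromA != df$chromB
  df
}

#' Write loops as BEDPE + gene
#' @param loops data.frame as returned by [read_loops()].
#' @param path Output path.
#' @export
write_loops <- function(loops, path) {
  keep <- intersect(c("chromA", "startA", "endA", "chromB", "startB", "endB",
                      "gene", "cell_type"), names(loops))
  utils::write.table(loops[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Regularize an LD correlation matrix
#'
#' Symmetrizes `R` as `(R + t(R)) / 2`; if the smallest eigenvalue is
#' negative, adds `ridge` to the diagonal and rescales back to a correlation
#' matrix (unit diagonal). The result is positive semi-definite.
#'
#' @param R Square numeric matrix of LD correlations.
#' @param ridge Ridge added to the diagonal when `R` is indefinite
#'   (default 1e-4).
#' @return Symmetric PSD correlation matrix with unit diagonal.
#' @export
regularize_ld <- function(R, ridge = 1e-4) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("LD matrix must be square")
  R <- (R + t(R)) / 2
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0) {
    R <- R + diag(ridge - ev_min, nrow(R))
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
  }
  diag(R) <- 1
  R
}

#' Load and regularize an LD matrix from disk
#'
#' Reads a whitespace-delimited square matrix plus a sidecar file of SNP ids
#' (one per line, default `<path>.ids`), checks shape agreement, and applies
#' [regularize_ld()].
#'
#' @param path Path to the matrix file.
#' @param ids_path Path to the SNP id sidecar (default `paste0(path, ".ids")`).
#' @param ridge Ridge for [regularize_ld()].
#' @return Correlation matrix with SNP ids as dimnames.
#' @export
load_and_regularize_ld <- function(path, ids_path = paste0(path, ".ids"),
                                   ridge = 1e-4) {
  R <- as.matrix(utils::read.table(path, header = FALSE))
  ids <- readLines(ids_path)
  ids <- ids[nzchar(ids)]
  if (nrow(R) != ncol(R)) stop("LD matrix must be square, got ",
                               nrow(R), " x ", ncol(R))
  if (length(ids) != nrow(R)) {
    stop("LD id list length (", length(ids), ") does not match matrix size (",
         nrow(R), ")")
  }
  R <- regularize_ld(R, ridge = ridge)
  dimnames(R) <- list(ids, ids)
  R
}

#' Write an LD matrix with id sidecar
#' @param R Correlation matrix with SNP-id dimnames.
#' @param path Output path (ids go to `paste0(path, ".ids")`).
#' @export
write_ld <- function(R, path) {
  utils::write.table(format(R, digits = 10, trim = TRUE), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(R), paste0(path, ".ids"))
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: `gene`, `chrom`, `tss`, `strand`, `biotype`,
#' `exons`. The `exons` column encodes 0-based half-open exon intervals as
#' `start-end` pairs separated by `,` (empty allowed).
#'
#' @param path Path to the annotation TSV.
#' @return list with `genes` (data.frame gene/chrom/tss/strand/biotype) and
#'   `exons` (data.frame gene/chrom/start/end).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene", "chrom", "tss", "strand", "biotype", "exons")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("gene annotation missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  exon_rows <- lapply(seq_len(nrow(df)), function(i) {
    ex <- df$exons[i]
    if (is.na(ex) || !nzchar(ex)) return(NULL)
    parts <- strsplit(strsplit(ex, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    data.frame(gene = df$gene[i], chrom = df$chrom[i],
               start = as.integer(vapply(parts, `[[`, character(1), 1L)),
               end = as.integer(vapply(parts, `[[`, character(1), 2L)),
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, exon_rows)
  if (is.null(exons)) {
    exons <- data.frame(gene = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  list(genes = df[, c("gene", "chrom", "tss", "strand", "biotype")],
       exons = exons)
}

#' Write a gene annotation table
#' @param genes data.frame gene/chrom/tss/strand/biotype.
#' @param exons data.frame gene/chrom/start/end.
#' @param path Output path.
#' @export
write_gene_annotation <- function(genes, exons, path) {
  ex_str <- vapply(genes$gene, function(g) {
    e <- exons[exons$gene == g, , drop = FALSE]
    if (nrow(e) == 0L) return("")
    paste(paste0(e$start, "-", e$end), collapse = ",")
  }, character(1))
  out <- cbind(genes, exons = ex_str)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL table (snp_id, gene, tissue)
#' @param path Path to a TSV with header.
#' @return data.frame with columns `snp_id`, `gene`, `tissue`.
#' @export
read_eqtl <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("snp_id", "gene", "tissue"), names(df))
  if (length(missing_cols) > 0L) {
    stop("eQTL table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read an activity-by-contact (ABC) table
#' @param path TSV with header: chrom, start, end, gene, score, cell_type.
#' @return data.frame with those columns.
#' @export
read_abc <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "gene", "score", "cell_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("ABC table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("ABC table has start >= end")
  df
}

#' Pipeline configuration
#'
#' Builds a validated configuration list for the full pipeline. Unknown
#' arguments are rejected.
#'
#' @param L Maximum number of single effects per LD block (default 10).
#' @param coverage Credible-set coverage (default 0.95).
#' @param min_purity Minimum absolute pairwise LD among credible-set members
#'   (default 0.5).
#' @param prior_variance Effect-size prior variance grid for the enrichment
#'   step (default 0.04).
#' @param sig_threshold Genome-wide significance threshold used to select LD
#'   blocks (default 5e-8).
#' @param ridge LD regularization ridge.
#' @param seed Integer seed recorded in logs.
#' @param paths Optional named list of input paths.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(L = 10L, coverage = 0.95, min_purity = 0.5,
                            prior_variance = 0.04, sig_threshold = 5e-8,
                            ridge = 1e-4, seed = 1L, paths = list()) {
  stopifnot(coverage > 0, coverage < 1, L >= 1, sig_threshold > 0,
            all(prior_variance > 0))
  structure(list(L = as.integer(L), coverage = coverage,
                 min_purity = min_purity, prior_variance = prior_variance,
                 sig_threshold = sig_threshold, ridge = ridge,
                 seed = as.integer(seed), paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return `pipeline_config` object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs; use JSON")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Write a run log with seed and config hash
#'
#' Records the timestamp, seed and a content hash of the configuration, so a
#' run can be tied to its exact settings.
#'
#' @param config `pipeline_config` object.
#' @param path Log file path.
#' @export
write_run_log <- function(config, path) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  hash <- sum(utf8ToInt(as.character(cfg_json)) *
                seq_along(utf8ToInt(as.character(cfg_json)))) %% 2147483647
  writeLines(c(paste0("time\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               paste0("seed\t", config$seed),
               paste0("config_hash\t", hash),
               paste0("config\t", cfg_json)), path)
  invisible(path)
}

# SNP positions (1-based) -> GRanges of width 1 at pos-1 in 0-based terms;
# GRanges is 1-based closed, so a SNP at pos p is [p, p] and a BED interval
# [s, e) is [s+1, e].
snp_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos))
}

bed_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
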
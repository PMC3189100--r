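#' Paths to bundled example data
#'
#' Small plain-text fixtures shipped with the package: the nine tryptophan
#' metabolism log2 ratios from a tryptophan-enrichment experiment
#' (`gsm513_trp_expression.tsv`) together with a synthetic miniature
#' membership (`trp_mini_synthetic.gmt`), and a synthetic opposing-module
#' pair in the glycolysis/gluconeogenesis mould
#' (`glyco_modules_synthetic.gmt`, `glyco_opposing_pairs_synthetic.tsv`).
#'
#' @param file File name, or `NULL` to list the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' pathalloc_example()
#' read_expression(pathalloc_example("gsm513_trp_expression.tsv"))
#' @export
pathalloc_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pathalloc")))
  }
  path <- system.file("extdata", file, package = "pathalloc")
  if (!nzchar(path)) abort(sprintf("no bundled file called '%s'.", file))
  path
}

#' Read gene sets from a GMT or two-column TSV file
#'
#' GMT dialect: one set per line, tab-separated; field 1 is the set
#' identifier, field 2 a description (ignored), fields 3+ the gene
#' identifiers. TSV dialect: two columns, gene identifier then set
#' identifier, no header. `"auto"` picks GMT for a `.gmt` extension.
#' Duplicate (gene, set) pairs collapse to one membership with a warning;
#' gene and set order follow first appearance.
#'
#' @param path File path.
#' @param format `"auto"`, `"gmt"` or `"tsv"`.
#' @return A tibble with columns `gene` and `pathway`, ready for
#'   [pathway_membership()].
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L || all(!nzchar(lines))) {
    abort(sprintf("empty gene-set file: %s", path))
  }
  if (format == "gmt") {
    recs <- strsplit(lines, "\t", fixed = TRUE)
    out <- vector("list", length(recs))
    for (k in seq_along(recs)) {
      f <- recs[[k]]
      if (!nzchar(lines[k])) next
      if (length(f) < 3L) {
        abort(sprintf("line %d of %s: GMT records need >= 3 fields.", k, path))
      }
      out[[k]] <- tibble::tibble(gene = f[-(1:2)], pathway = f[1L])
    }
    sets <- dplyr::bind_rows(out)
  } else {
    recs <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(recs) < 2L & nzchar(lines))
    if (length(bad) > 0L) {
      abort(sprintf("line %d of %s: expected two tab-separated columns.",
                    bad[1L], path))
    }
    keep <- nzchar(lines)
    sets <- tibble::tibble(
      gene = vapply(recs[keep], `[`, character(1L), 1L),
      pathway = vapply(recs[keep], `[`, character(1L), 2L)
    )
  }
  dup <- duplicated(paste(sets$gene, sets$pathway, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("%s: collapsed %d duplicate gene-set pair(s).", path, sum(dup)))
    sets <- sets[!dup, ]
  }
  sets
}

#' Read a two-column expression table (gene, log2 ratio)
#'
#' Tab-separated, one gene per row. A header line is auto-detected (second
#' field not numeric). Duplicate gene identifiers and non-numeric ratios
#' are format errors reported with their line number.
#'
#' @param path File path.
#' @return A tibble with columns `gene` and `log2_ratio`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) abort(sprintf("empty expression file: %s", path))
  recs <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(recs) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d of %s: expected two tab-separated columns.",
                  bad[1L], path))
  }
  first_ratio <- suppressWarnings(as.numeric(recs[[1L]][2L]))
  start <- if (is.na(first_ratio)) 2L else 1L
  if (start > length(recs)) abort(sprintf("no data rows in %s.", path))
  rows <- recs[start:length(recs)]
  gene <- vapply(rows, `[`, character(1L), 1L)
  ratio_chr <- vapply(rows, `[`, character(1L), 2L)
  ratio <- suppressWarnings(as.numeric(ratio_chr))
  if (anyNA(ratio)) {
    abort(sprintf("line %d of %s: non-numeric log2 ratio '%s'.",
                  which(is.na(ratio))[1L] + start - 1L, path,
                  ratio_chr[which(is.na(ratio))[1L]]))
  }
  if (anyDuplicated(gene)) {
    abort(sprintf("line %d of %s: duplicate gene '%s'.",
                  which(duplicated(gene))[1L] + start - 1L, path,
                  gene[which(duplicated(gene))[1L]]))
  }
  tibble::tibble(gene = gene, log2_ratio = ratio)
}

#' Read a two-column table of opposing module pairs
#'
#' @param path Tab-separated file, two module identifiers per line.
#' @return A tibble with columns `module_a`, `module_b`.
#' @export
read_opposing_pairs <- function(path) {
  sets <- read_gene_sets(path, format = "tsv")
  tibble::tibble(module_a = sets$gene, module_b = sets$pathway)
}

# --------------------------------------------------------------------------
# Writers. Every output starts with comment lines carrying the package
# version, the run seed and a checksum of the configuration, so identical
# runs produce byte-identical files.

# 31-bit polynomial checksum of the flattened config, as 8 hex digits
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(names(config), unlist(config),
                           sep = "=", collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(fit) {
  c(
    sprintf("# pathalloc %s", as.character(packageVersion("pathalloc"))),
    sprintf("# seed=%d method=%s mode=%s", fit$seed, fit$method, fit$mode),
    sprintf("# config=%s", config_hash(fit$config))
  )
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, open = "wb")  # binary mode: LF endings everywhere
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Write an allocation in long TSV form
#'
#' One row per gene-pathway membership: whether the gene is allocated
#' there and its expression state. Diff-friendly and joinable.
#'
#' @param fit An `allocation_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(fit, path) {
  stopifnot(inherits(fit, "allocation_fit"))
  write_tsv_with_header(tidy(fit), path, output_header(fit))
}

#' Write the per-pathway allocation report
#'
#' @inheritParams write_allocation
#' @return `path`, invisibly.
#' @export
write_pathway_report <- function(fit, path) {
  stopifnot(inherits(fit, "allocation_fit"))
  write_tsv_with_header(pathway_summary(fit), path, output_header(fit))
}

#' Write the fitness trace of a search
#'
#' @inheritParams write_allocation
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "allocation_fit"))
  write_tsv_with_header(fitness_trace(fit), path, output_header(fit))
}

#' Write an exact Hamming null distribution
#'
#' @param null A `hamming_null`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  stopifnot(inherits(null, "hamming_null"))
  header <- c(
    sprintf("# pathalloc %s", as.character(packageVersion("pathalloc"))),
    sprintf("# n_genes=%d total_pairs=%s", attr(null, "n_genes"),
            format(attr(null, "total_pairs"), scientific = FALSE))
  )
  df <- tibble::as_tibble(null)
  df$probability <- sprintf("%.12g", df$probability)
  write_tsv_with_header(df, path, header)
}
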
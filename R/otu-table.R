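#' Construct an OTU count table
#'
#' An `otu_table` holds a non-negative integer count matrix (taxa in rows,
#' samples in columns) plus an optional taxonomy lineage string per taxon
#' (rank-delimited, e.g. `"k__Archaea; p__Euryarchaeota"`).
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   row names (taxon ids) and column names (sample ids).
#' @param taxonomy Optional character vector of lineage strings, one per
#'   taxon, in row order (or named by taxon id).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop("duplicate taxon id: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) taxonomy <- unname(taxonomy[rownames(counts)])
    if (length(taxonomy) != nrow(counts)) {
      stop("`taxonomy` must have one lineage per taxon", call. = FALSE)
    }
    taxonomy <- as.character(taxonomy)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d taxa x %d samples, %s reads%s\n",
              n_taxa(x), n_samples(x), format(sum(x$counts), big.mark = ","),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Tidy an OTU table into long format
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A tibble with columns `taxon_id`, `sample_id`, `count` and, when
#'   taxonomy is present, `taxonomy`.
#' @export
tidy.otu_table <- function(x, ...) {
  out <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(out) <- c("taxon_id", "sample_id", "count")
  out$count <- as.integer(out$count)
  if (!is.null(x$taxonomy)) {
    out$taxonomy <- x$taxonomy[match(out$taxon_id, rownames(x$counts))]
  }
  out
}

#' Read an OTU table from TSV or BIOM-JSON
#'
#' The TSV dialect has taxon ids in the first column, sample ids in the header
#' row, and an optional trailing `taxonomy` column. BIOM files are read through
#' the biomformat package (format 1.0, dense or sparse).
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param transpose For TSV only: set `TRUE` if the file has samples in rows
#'   and taxa in columns.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("no taxa: table body is empty", call. = FALSE)
    if (ncol(df) < 2L) stop("malformed header: need taxon id column plus sample columns",
                            call. = FALSE)
    taxonomy <- NULL
    if (tolower(names(df)[ncol(df)]) == "taxonomy") {
      taxonomy <- as.character(df[[ncol(df)]])
      df <- df[, -ncol(df), drop = FALSE]
    }
    if (transpose) {
      ids <- as.character(df[[1]])
      m <- t(as.matrix(df[, -1, drop = FALSE]))
      colnames(m) <- ids
    } else {
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- as.character(df[[1]])
    }
    if (!is.numeric(m)) {
      stop("non-integer counts: table body contains non-numeric entries", call. = FALSE)
    }
    otu_table(m, taxonomy = taxonomy)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    taxonomy <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.null(om)) NULL
      else if (is.data.frame(om)) {
        apply(om, 1, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = "; "))
      } else {
        vapply(om, function(r) paste(unlist(r), collapse = "; "), character(1))
      }
    }, error = function(e) NULL)
    if (!is.null(taxonomy) && all(!nzchar(taxonomy))) taxonomy <- NULL
    otu_table(m, taxonomy = taxonomy)
  }
}

#' Write an OTU table to TSV or BIOM-JSON
#'
#' @inheritParams read_otu_table
#' @param x An `otu_table`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "otu_table"))
  if (format == "tsv") {
    df <- data.frame(`#OTU ID` = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(x$taxonomy)) df$taxonomy <- x$taxonomy
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    om <- NULL
    if (!is.null(x$taxonomy)) {
      om <- data.frame(taxonomy = x$taxonomy, row.names = rownames(x$counts),
                       stringsAsFactors = FALSE)
    }
    b <- biomformat::make_biom(x$counts, observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Per-sample read totals
#'
#' @param x An `otu_table`.
#' @return A tibble with columns `sample_id` and `total`, in sample order,
#'   carrying the grand total in attribute `"grand_total"`.
#' @export
sample_totals <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- colSums(x$counts)
  out <- tibble::tibble(sample_id = colnames(x$counts), total = as.integer(tot))
  attr(out, "grand_total") <- sum(tot)
  out
}

.rank_names <- c("domain", "phylum", "class", "order", "family", "genus")

#' Collapse an OTU table to a taxonomic rank
#'
#' Taxa sharing the same lineage prefix through `rank` are summed. Taxa with no
#' assignment at `rank` (lineage too short, or an empty rank field such as
#' `"p__"`) are pooled into a single `unassigned_at_<rank>` row. The grand
#' total is conserved exactly.
#'
#' @param x An `otu_table` with taxonomy.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An `otu_table` with one row per rank-level group.
#' @export
collapse_to_rank <- function(x, rank) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$taxonomy)) stop("OTU table has no taxonomy", call. = FALSE)
  rank <- match.arg(rank, .rank_names)
  # rank located by its lineage prefix letter (domain accepts k__ or d__)
  prefix <- c(domain = "k|d", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g")[[rank]]
  pat <- paste0("^(", prefix, ")__")
  key <- vapply(x$taxonomy, function(lin) {
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    at <- grep(pat, parts)
    if (length(at) == 0) return(NA_character_)
    at <- at[1]
    # an empty rank field like "p__" is no assignment
    if (!nzchar(sub("^[a-z]__", "", parts[at]))) return(NA_character_)
    paste(parts[seq_len(at)], collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
  key[is.na(key)] <- paste0("unassigned_at_", rank)
  groups <- unique(key)
  m <- rowsum(x$counts, group = factor(key, levels = groups), reorder = FALSE)
  otu_table(m, taxonomy = groups)
}

#' Relative abundances
#'
#' @param x An `otu_table` in which every sample has at least one read.
#' @return A numeric matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0)) {
    stop("zero-total sample: ", paste(colnames(x$counts)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(x$counts, 2, tot, "/")
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each retained sample's counts are a uniform subsample without replacement of
#' exactly `depth` reads. Samples with fewer than `depth` reads are dropped and
#' recorded in the rarefaction log (attribute `"rarefaction_log"`, a tibble
#' with one row per input sample). The draw is deterministic for a fixed seed.
#'
#' @param x An `otu_table`.
#' @param depth Target depth (reads per sample), `>= 1`.
#' @param seed Integer seed for the subsampling draw.
#' @return A rarefied `otu_table`; every column sums to `depth`.
#' @export
rarefy <- function(x, depth, seed) {
  stopifnot(inherits(x, "otu_table"), depth >= 1)
  depth <- as.integer(depth)
  tot <- colSums(x$counts)
  keep <- tot >= depth
  log <- tibble::tibble(
    sample_id = colnames(x$counts),
    total = as.integer(unname(tot)),
    depth = depth,
    status = unname(ifelse(keep, "retained", "dropped"))
  )
  if (!any(keep)) {
    stop("rarefaction depth ", depth, " drops all samples", call. = FALSE)
  }
  m <- x$counts[, keep, drop = FALSE]
  nt <- nrow(m)
  sub <- withr::with_seed(seed, {
    apply(m, 2, function(cnt) {
      if (sum(cnt) == depth) return(cnt)
      drawn <- sample(rep.int(seq_len(nt), cnt), depth)
      tabulate(drawn, nbins = nt)
    })
  })
  dimnames(sub) <- list(rownames(m), colnames(m))
  out <- otu_table(sub, taxonomy = x$taxonomy)
  attr(out, "rarefaction_log") <- log
  out
}

#' @rdname rarefy
#' @export
rarefaction_log <- function(x) attr(x, "rarefaction_log")
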
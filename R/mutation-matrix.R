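# The samples x driver-mutation-types presence matrix. Cells are 1
# (present), 0 (absent among assayed samples) or NA (class not assayed for
# that sample) -- NA never counts toward a denominator.

# expand a catalog into one interval row per (mutation_type, interval),
# including pooled auxiliary loci (e.g. an enhancer pooled with a gene body)
catalog_intervals <- function(catalog) {
  purrr::pmap_dfr(
    list(catalog$mutation_type, catalog$chromosome, catalog$start_bp,
         catalog$end_bp, catalog$pooled_loci),
    function(mt, chrom, start, end, pooled) {
      own <- tibble(mutation_type = mt, chrom = chrom,
                    start = start, end = end)
      extra <- parse_loci(pooled)
      if (nrow(extra) > 0) {
        own <- bind_rows(own, tibble(mutation_type = mt, chrom = extra$chrom,
                                     start = extra$start, end = extra$end))
      }
      own
    }
  )
}

#' Build the samples x driver-mutation-types matrix
#'
#' Combines harmonized CNA segments, SNV calls and SV calls into a wide
#' binary presence matrix with one column per catalog mutation type.
#' Denominator bookkeeping follows the assay masks: a cell is `NA` when the
#' sample was not assayed for that mutation class, so class denominators
#' are always the number of samples with that class assayed, never the
#' cohort size.
#'
#' Rules applied:
#' * a CNA segment hits an entry if it overlaps the gene span or any pooled
#'   locus by at least 1 bp and its call matches the entry's direction;
#' * SNV calls are matched by `gene` to the catalog `gene_id` of the same
#'   class (`SNV` coding by default; an optional `class` column may route
#'   calls to `ncSNV` entries);
#' * an SV hits an entry if either breakpoint interval overlaps the entry's
#'   span or pooled loci; entries with an `sv_subtype_filter` only accept
#'   the listed subtypes, unrestricted entries accept any subtype;
#' * multiple hits in one sample/class collapse to a single presence —
#'   prevalence is per patient.
#'
#' Calls naming a sample absent from `samples` are an error; calls for a
#' sample lacking that assay class are rejected with a warning naming the
#' count.
#'
#' @param calls A list with any of `cna` (tibble: `sample_id`, `chrom`,
#'   `start`, `end`, `call`; see [read_seg()]), `snv` (`sample_id`, `gene`,
#'   optionally `class`), `sv` (`sample_id`, `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `sv_type`).
#' @param catalog A validated driver catalog ([read_driver_catalog()]).
#' @param samples A validated sample table ([validate_samples()]).
#' @return A tibble with `sample_id` followed by one integer column per
#'   mutation type (`"GENE:class"` ids), cells in `{0L, 1L, NA}`.
#' @export
build_mutation_matrix <- function(calls, catalog, samples) {
  samples <- validate_samples(samples)
  if (nrow(catalog) == 0) {
    return(tibble(sample_id = samples$sample_id))
  }

  # NA-mask initialisation from each sample's assayed classes
  cells <- matrix(NA_integer_, nrow = nrow(samples), ncol = nrow(catalog),
                  dimnames = list(samples$sample_id, catalog$mutation_type))
  for (j in seq_len(nrow(catalog))) {
    ac <- assay_class_of(catalog$class[j])
    assayed <- has_assay_class(samples$assayed_classes, ac)
    cells[assayed, j] <- 0L
  }

  mark_present <- function(sample_ids, mutation_types, what) {
    if (length(sample_ids) == 0) return(invisible(NULL))
    unknown <- setdiff(sample_ids, samples$sample_id)
    if (length(unknown) > 0) {
      abort(paste0(what, " call(s) reference unknown sample(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    idx <- cbind(match(sample_ids, samples$sample_id),
                 match(mutation_types, catalog$mutation_type))
    unassayed <- is.na(cells[idx])
    if (any(unassayed)) {
      warn(paste0(sum(unassayed), " ", what,
                  " call(s) rejected: sample not assayed for that class"))
      idx <- idx[!unassayed, , drop = FALSE]
    }
    cells[idx] <<- 1L
    invisible(NULL)
  }

  intervals <- catalog_intervals(catalog)

  if (!is.null(calls$cna) && nrow(calls$cna) > 0) {
    cna <- as_tibble(calls$cna) %>% filter(.data$call %in% c("gain", "loss"))
    targets <- intervals %>%
      inner_join(catalog %>% select("mutation_type", "class"),
                 by = "mutation_type") %>%
      filter(.data$class %in% c("CNA_gain", "CNA_loss")) %>%
      mutate(call = if_else(.data$class == "CNA_gain", "gain", "loss"))
    hits <- cna %>%
      inner_join(targets, by = c("chrom", "call"),
                 relationship = "many-to-many",
                 suffix = c("", ".gene")) %>%
      filter(intervals_overlap(.data$start, .data$end,
                               .data$start.gene, .data$end.gene)) %>%
      distinct(.data$sample_id, .data$mutation_type)
    mark_present(hits$sample_id, hits$mutation_type, "CNA")
  }

  if (!is.null(calls$snv) && nrow(calls$snv) > 0) {
    snv <- as_tibble(calls$snv)
    if (!"class" %in% names(snv)) snv$class <- "SNV"
    snv_catalog <- catalog %>%
      filter(.data$class %in% c("SNV", "ncSNV")) %>%
      select("gene_id", "class", "mutation_type")
    hits <- snv %>%
      inner_join(snv_catalog, by = c(gene = "gene_id", class = "class")) %>%
      distinct(.data$sample_id, .data$mutation_type)
    mark_present(hits$sample_id, hits$mutation_type, "SNV")
  }

  if (!is.null(calls$sv) && nrow(calls$sv) > 0) {
    sv <- as_tibble(calls$sv)
    sv_entries <- catalog %>% filter(.data$class == "SV")
    if (nrow(sv_entries) > 0) {
      sv_iv <- intervals %>%
        semi_join(sv_entries, by = "mutation_type") %>%
        left_join(sv_entries %>%
                    select("mutation_type", "sv_subtype_filter"),
                  by = "mutation_type")
      # one row per breakpoint so either end can hit the locus
      bp <- bind_rows(
        sv %>% select("sample_id", chrom = "chrom1", start = "start1",
                      end = "end1", "sv_type"),
        sv %>% select("sample_id", chrom = "chrom2", start = "start2",
                      end = "end2", "sv_type")
      )
      hits <- bp %>%
        inner_join(sv_iv, by = "chrom", relationship = "many-to-many",
                   suffix = c("", ".locus")) %>%
        filter(intervals_overlap(.data$start, .data$end,
                                 .data$start.locus, .data$end.locus)) %>%
        filter(purrr::map2_lgl(.data$sv_subtype_filter, .data$sv_type,
                               sv_subtype_allowed)) %>%
        distinct(.data$sample_id, .data$mutation_type)
      mark_present(hits$sample_id, hits$mutation_type, "SV")
    }
  }

  bind_cols(tibble(sample_id = samples$sample_id), as_tibble(cells))
}

sv_subtype_allowed <- function(filter, sv_type) {
  if (is.na(filter) || !nzchar(filter)) return(TRUE)
  tolower(trimws(sv_type)) %in% tolower(trimws(strsplit(filter, ",")[[1]]))
}

#' Write / read a mutation matrix in the package's TSV dialect
#'
#' Cells are written as `0`, `1` or `NA`; writing then re-reading is an
#' identity.
#'
#' @param matrix A mutation matrix tibble ([build_mutation_matrix()]).
#' @param path Output (or input) TSV path.
#' @return `write_mutation_matrix()` returns `path` invisibly;
#'   `read_mutation_matrix()` returns the matrix tibble.
#' @export
write_mutation_matrix <- function(matrix, path) {
  readr::write_tsv(matrix, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_mutation_matrix
#' @export
read_mutation_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}

# columns of `matrix` (less sample_id) as an integer matrix
matrix_cells <- function(matrix) {
  m <- as.matrix(matrix[setdiff(names(matrix), "sample_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- matrix$sample_id
  m
}
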
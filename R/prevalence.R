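# Mutation prevalence with Wald confidence intervals, per-gene combined
# prevalence and the propagation-of-error bookkeeping for unequal class
# denominators.

#' Wald 95% confidence interval for a proportion
#'
#' `p +/- 1.96 * sqrt(p * (1 - p) / n)`, clipped to `[0, 1]` after the
#' plus/minus computation.
#'
#' @param p_hat Proportion(s) in `[0, 1]`.
#' @param n Positive denominator(s), recycled along `p_hat`.
#' @return A tibble with columns `ci_low`, `ci_high`.
#' @export
#' @examples
#' wald_ci(395 / 555, 555) # ~ (0.674, 0.749)
#' wald_ci(2 / 1279, 1279) # lower bound clipped at 0
wald_ci <- function(p_hat, n) {
  if (any(n < 1)) abort("wald_ci: n must be >= 1")
  if (any(p_hat < 0 | p_hat > 1)) abort("wald_ci: p_hat must lie in [0, 1]")
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  tibble(
    ci_low = pmax(0, p_hat - half),
    ci_high = pmin(1, p_hat + half)
  )
}

#' Prevalence of one mutation type
#'
#' Proportion of assayed samples carrying the mutation; `NA` cells (class
#' not assayed) are excluded from the denominator.
#'
#' @param matrix A mutation matrix tibble.
#' @param mutation_type Column name (`"GENE:class"`).
#' @return One-row tibble: `mutation_type`, `numerator`, `denominator`,
#'   `p_hat`, `ci_low`, `ci_high`.
#' @export
class_prevalence <- function(matrix, mutation_type) {
  if (!mutation_type %in% names(matrix)) {
    abort(paste0("mutation type not in matrix: ", mutation_type))
  }
  col <- matrix[[mutation_type]]
  denominator <- sum(!is.na(col))
  if (denominator == 0) {
    abort(paste0("no assayed samples for ", mutation_type))
  }
  numerator <- sum(col == 1L, na.rm = TRUE)
  p_hat <- numerator / denominator
  ci <- wald_ci(p_hat, denominator)
  tibble(
    mutation_type = mutation_type, numerator = numerator,
    denominator = denominator, p_hat = p_hat,
    ci_low = ci$ci_low, ci_high = ci$ci_high
  )
}

#' Per-state prevalence table for every mutation type
#'
#' @param matrix A mutation matrix tibble.
#' @param samples Sample table with `sample_id` and `state`.
#' @return Tibble with one row per mutation type per disease state
#'   (`mutation_type`, `state`, `numerator`, `denominator`, `p_hat`,
#'   `ci_low`, `ci_high`); mutation types with no assayed samples in a
#'   state are omitted for that state.
#' @export
prevalence_table <- function(matrix, samples) {
  types <- setdiff(names(matrix), "sample_id")
  states <- sort(unique(samples$state))
  purrr::map_dfr(states, function(st) {
    sub <- matrix %>%
      semi_join(samples %>% filter(.data$state == st), by = "sample_id")
    purrr::map_dfr(types, function(mt) {
      if (all(is.na(sub[[mt]]))) return(NULL)
      class_prevalence(sub, mt) %>% mutate(state = st, .after = 1)
    })
  })
}

#' Combined per-gene prevalence across mutation classes
#'
#' A gene's combined prevalence is the proportion of samples carrying a
#' mutation of *any* class (CNA, SNV including non-coding, SV). Two methods:
#'
#' * `empirical_union` (default, exact): counts samples with at least one
#'   present cell across the gene's columns, over the denominator of
#'   samples assayed for at least one class.
#' * `eq3_literal`: evaluates the closed-form bookkeeping
#'   `(P_CNA + P_SNV + P_SV) - (P_CNA&SNV + P_CNA&SV + P_SNV&SV +
#'   P_CNA&SNV&SV)` with each single computed on its own class denominator
#'   and each joint ("at least both") on the samples assayed for all its
#'   classes. Note this subtracts rather than adds the triple term, so it
#'   is not standard inclusion-exclusion; it is retained for reproduction
#'   of the published bookkeeping.
#'
#' Propagation of error across class CIs (`PE = sqrt(ci_high^2 +
#' ci_low^2)` per term; variance `sqrt(sum(PE_singles) - sum(PE_joints))`,
#' `NaN` with a flag when the radicand is negative) is reported alongside.
#'
#' @param matrix Mutation matrix tibble.
#' @param gene_id Gene identifier present in the catalog columns.
#' @param method `"empirical_union"` or `"eq3_literal"`.
#' @return One-row tibble: `gene_id`, `method`, `p_gene`, `numerator`,
#'   `denominator`, `ci_low`, `ci_high`, `variance_pe`, `pe_flag`, and a
#'   list-column `pe_by_class`.
#' @export
combined_gene_prevalence <- function(matrix, gene_id,
                                     method = c("empirical_union",
                                                "eq3_literal")) {
  method <- match.arg(method)
  types <- setdiff(names(matrix), "sample_id")
  info <- split_mutation_type(types) %>% mutate(mutation_type = types)
  own <- info %>% filter(.data$gene_id == !!gene_id)
  if (nrow(own) == 0) abort(paste0("gene not in matrix: ", gene_id))

  cells <- matrix_cells(matrix)[, own$mutation_type, drop = FALSE]
  buckets <- class_bucket_of(own$class)
  # per-bucket presence (1/0/NA) per sample: present if any class column
  # in the bucket is 1, absent if all assayed columns are 0
  bucket_presence <- vapply(unique(buckets), function(b) {
    sub <- cells[, buckets == b, drop = FALSE]
    any_present <- apply(sub, 1, function(x) {
      if (all(is.na(x))) NA_integer_ else as.integer(any(x == 1L, na.rm = TRUE))
    })
    any_present
  }, integer(nrow(cells)))
  bucket_presence <- matrix(bucket_presence, nrow = nrow(cells),
                            dimnames = list(rownames(cells), unique(buckets)))
  bnames <- colnames(bucket_presence)

  assayed <- !is.na(bucket_presence)
  if (length(bnames) > 1) {
    pairs <- utils::combn(bnames, 2)
    disjoint <- apply(pairs, 2, function(pr) {
      !any(assayed[, pr[1]] & assayed[, pr[2]])
    })
    if (any(disjoint)) {
      warn(paste0("gene ", gene_id, ": some mutation classes have disjoint ",
                  "assayed sample sets; class terms use their own ",
                  "denominators"))
    }
  }

  # singles and joints ("at least both") on their own denominators
  term_sets <- purrr::flatten(purrr::map(seq_along(bnames), function(k) {
    purrr::array_branch(utils::combn(bnames, k), 2)
  }))
  terms <- purrr::map_dfr(term_sets, function(set) {
    rows <- rowSums(!assayed[, set, drop = FALSE]) == 0
    denom <- sum(rows)
    num <- if (denom == 0) 0L else {
      sum(rowSums(bucket_presence[rows, set, drop = FALSE] == 1L) ==
            length(set))
    }
    p <- if (denom == 0) NA_real_ else num / denom
    ci <- if (denom == 0) tibble(ci_low = NA_real_, ci_high = NA_real_) else
      wald_ci(p, denom)
    tibble(term = paste(set, collapse = "&"), k = length(set),
           numerator = num, denominator = denom, p = p,
           ci_low = ci$ci_low, ci_high = ci$ci_high)
  })

  pe <- error_propagation(terms)

  union_assayed <- rowSums(assayed) > 0
  union_denom <- sum(union_assayed)
  union_num <- sum(rowSums(bucket_presence == 1L, na.rm = TRUE)[union_assayed]
                   > 0)

  p_gene <- if (method == "empirical_union") {
    union_num / union_denom
  } else {
    singles <- terms %>% filter(.data$k == 1)
    joints <- terms %>% filter(.data$k > 1)
    sum(singles$p, na.rm = TRUE) - sum(joints$p, na.rm = TRUE)
  }
  ci <- wald_ci(min(max(p_gene, 0), 1), union_denom)

  tibble(
    gene_id = gene_id, method = method, p_gene = p_gene,
    numerator = union_num, denominator = union_denom,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    variance_pe = pe$variance_pe, pe_flag = pe$flag,
    pe_by_class = list(pe$pe_by_class)
  )
}

#' Propagation of error across class confidence intervals
#'
#' `PE_term = sqrt(ci_high^2 + ci_low^2)` for every class or class
#' combination, and the combined variance term
#' `sqrt(sum(PE_singles) - sum(PE_joints))`, evaluated literally on CI
#' *bounds* (not half-widths). When the radicand is negative the variance
#' is returned as `NaN` with `flag = TRUE` rather than erroring.
#'
#' @param terms Tibble with columns `term` (e.g. `"CNA"`, `"CNA&SNV"`),
#'   `k` (number of classes in the term), `ci_low`, `ci_high`.
#' @return List with `pe_by_class` (named numeric), `variance_pe`, `flag`.
#' @export
error_propagation <- function(terms) {
  pe <- sqrt(terms$ci_high^2 + terms$ci_low^2)
  names(pe) <- terms$term
  singles <- sum(pe[terms$k == 1], na.rm = TRUE)
  joints <- sum(pe[terms$k > 1], na.rm = TRUE)
  radicand <- singles - joints
  flag <- is.finite(radicand) && radicand < 0
  variance_pe <- if (flag) NaN else sqrt(radicand)
  list(pe_by_class = pe, variance_pe = variance_pe, flag = flag)
}
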
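#' Expression study container
#'
#' Bundles a gene x sample FPKM matrix with per-sample metadata. Cohorts
#' (normal / primary / metastatic per cancer type) are populated by
#' [build_cohorts()].
#'
#' @param matrix numeric matrix, rows = gene symbols, columns = sample IDs,
#'   values non-negative FPKM.
#' @param metadata data frame with columns `sample_id`, `cancer_type`,
#'   `source` (`"normal"` or `"tumour"`), `T`, `N`, `M` (TNM codes).
#' @return An `expression_study` list (`matrix`, `metadata`, `cohorts`).
#' @export
expression_study <- function(matrix, metadata) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  stopifnot(all(c("sample_id", "cancer_type", "source", "T", "N", "M") %in%
                names(metadata)))
  if (any(matrix < 0)) stop("FPKM values must be non-negative")
  structure(list(matrix = matrix, metadata = metadata, cohorts = NULL),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$cohorts)) {
    for (ct in names(x$cohorts)) {
      co <- x$cohorts[[ct]]
      cat(sprintf("  %s: normal %d, primary %d, metastatic %d\n", ct,
                  length(co$normal), length(co$primary), length(co$metastatic)))
    }
  }
  invisible(x)
}

#' Classify a tumour sample by its TNM code
#'
#' Implements the staging rule used to split tumour samples into disease
#' stages: any missing component (`TX`/`NX`/`MX`) excludes the sample;
#' otherwise `N0` and `M0` (any T) is primary-stage disease, and nodal
#' spread `N1`/`N2`/`N3` (any M) is metastasized disease. A sample with
#' `N0` but `M1` matches neither printed rule; in `"strict"` mode it is
#' excluded with a warning, in `"inclusive"` mode it is treated as
#' metastasized on the strength of its distant metastasis.
#'
#' Sub-stage suffixes (e.g. `T2a`, `N1b`) are tolerated: only the leading
#' two characters of each code are interpreted.
#'
#' @param t,n,m character vectors of TNM codes (equal length), each element
#'   starting with `T`, `N`, `M` respectively.
#' @param mode `"strict"` (literal rules) or `"inclusive"`.
#' @param sample_id optional sample names used in error messages.
#' @return Character vector: `"primary"`, `"metastasized"`, or `"excluded"`.
#' @examples
#' classify_tnm("T2", "N0", "M0")   # primary
#' classify_tnm("T3", "N2", "M1")   # metastasized
#' classify_tnm("T1", "NX", "M0")   # excluded
#' @export
classify_tnm <- function(t, n, m, mode = c("strict", "inclusive"),
                         sample_id = NULL) {
  mode <- match.arg(mode)
  t <- as.character(t); n <- as.character(n); m <- as.character(m)
  stopifnot(length(t) == length(n), length(n) == length(m))
  ids <- sample_id %||% as.character(seq_along(t))
  bad <- !startsWith(t, "T") | !startsWith(n, "N") | !startsWith(m, "M") |
    nchar(t) < 2 | nchar(n) < 2 | nchar(m) < 2
  if (any(bad)) {
    stop("malformed TNM code for sample ", ids[which(bad)[1]], ": (",
         t[which(bad)[1]], ", ", n[which(bad)[1]], ", ", m[which(bad)[1]], ")")
  }
  tc <- substr(t, 1, 2); nc <- substr(n, 1, 2); mc <- substr(m, 1, 2)
  out <- rep("excluded", length(t))
  missing_code <- tc == "TX" | nc == "NX" | mc == "MX"
  primary <- !missing_code & nc == "N0" & mc == "M0"
  meta <- !missing_code & nc %in% c("N1", "N2", "N3")
  out[primary] <- "primary"
  out[meta] <- "metastasized"
  odd <- !missing_code & !primary & !meta
  if (any(odd)) {
    if (mode == "inclusive") {
      out[odd] <- "metastasized"
    } else {
      warning(sum(odd), " sample(s) (e.g. N0 with M1) match no staging rule; excluded")
    }
  }
  out
}

#' Resolve cohorts from sample metadata
#'
#' Populates, per cancer type, the normal / primary / metastatic sample-ID
#' lists. Samples whose TNM code contains a missing component (X) enter no
#' cohort. Normal-source samples form the normal cohort; tumour samples are
#' staged by [classify_tnm()]. Cohort sizes are reported via [message()].
#'
#' @param study an [expression_study()] whose metadata covers every matrix
#'   column.
#' @param mode staging mode passed to [classify_tnm()].
#' @return The study with `cohorts` populated.
#' @export
build_cohorts <- function(study, mode = "strict") {
  stopifnot(inherits(study, "expression_study"))
  md <- study$metadata
  absent <- setdiff(colnames(study$matrix), md$sample_id)
  if (length(absent) > 0) {
    stop("metadata missing for sample(s): ", paste(utils::head(absent, 5), collapse = ", "))
  }
  md <- md[md$sample_id %in% colnames(study$matrix), , drop = FALSE]
  has_x <- grepl("X", substr(md$T, 1, 2)) | grepl("X", substr(md$N, 1, 2)) |
    grepl("X", substr(md$M, 1, 2))
  stage <- rep("excluded", nrow(md))
  normal <- md$source == "normal" & !has_x
  stage[normal] <- "normal"
  tum <- md$source != "normal"
  if (any(tum)) {
    stage[tum] <- classify_tnm(md$T[tum], md$N[tum], md$M[tum], mode = mode,
                               sample_id = md$sample_id[tum])
  }
  cohorts <- lapply(split(seq_len(nrow(md)), md$cancer_type), function(i) {
    list(normal = md$sample_id[i][stage[i] == "normal"],
         primary = md$sample_id[i][stage[i] == "primary"],
         metastatic = md$sample_id[i][stage[i] == "metastasized"])
  })
  for (ct in names(cohorts)) {
    co <- cohorts[[ct]]
    message(sprintf("%s cohorts: normal %d, primary %d, metastatic %d", ct,
                    length(co$normal), length(co$primary), length(co$metastatic)))
  }
  study$cohorts <- cohorts
  study
}

#' Fold change between two expression cohorts
#'
#' Ratio of cohort mean expressions across a transition, with `group_b` the
#' later state: `fc = (mean_b + eps) / (mean_a + eps)`. The pseudocount
#' `eps` (default 1e-3 FPKM) guards zero means and is applied to the means
#' only; its use on a zero mean is reported via [message()].
#'
#' @param group_a,group_b non-empty numeric FPKM vectors (earlier / later
#'   state of the transition).
#' @param eps pseudocount added to both means.
#' @return List with `fc` and `log2fc`.
#' @export
fold_change <- function(group_a, group_b, eps = 1e-3) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  ma <- mean(group_a); mb <- mean(group_b)
  if (ma == 0 || mb == 0) {
    message("zero cohort mean encountered; pseudocount eps = ", eps, " applied")
  }
  fc <- (mb + eps) / (ma + eps)
  list(fc = fc, log2fc = log2(fc))
}

#' Kruskal-Wallis test between expression cohorts
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on (groups - 1) degrees of freedom. When every value is
#' identical there is no rank separation and the result is `H = 0, p = 1`
#' by convention.
#'
#' @param groups list of >= 2 non-empty numeric vectors (total n >= 3).
#' @return List with `h_stat` and `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) > 0), sum(lengths(groups)) >= 3)
  values <- unlist(groups)
  if (length(unique(values)) == 1) return(list(h_stat = 0, p_value = 1))
  grouping <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, grouping)
  list(h_stat = unname(kt$statistic), p_value = kt$p.value)
}

#' Stratify a gene by fold change and significance
#'
#' Applies the printed significance bands literally (all inequalities
#' strict):
#' * high: |log2FC| > 2 and P < 0.001
#' * medium: 1 < |log2FC| < 2 and 0.001 < P < 0.01
#' * low: 1 < |log2FC| < 2 and 0.01 < P < 0.05
#' * non-significant: P > 0.05
#'
#' Combinations matching no band (e.g. |log2FC| > 2 with 0.001 < P < 0.05)
#' are labelled `unclassified` rather than silently widening a band.
#'
#' @param log2fc,p numeric vectors (recycled to equal length).
#' @return Character vector of tiers.
#' @export
stratify <- function(log2fc, p) {
  k <- max(length(log2fc), length(p))
  log2fc <- rep_len(log2fc, k); p <- rep_len(p, k)
  a <- abs(log2fc)
  tier <- rep("unclassified", k)
  tier[a > 2 & p < 0.001] <- "high"
  tier[a > 1 & a < 2 & p > 0.001 & p < 0.01] <- "medium"
  tier[a > 1 & a < 2 & p > 0.01 & p < 0.05] <- "low"
  tier[tier == "unclassified" & p > 0.05] <- "non_significant"
  tier
}

#' Call differential-expression hits for final candidates
#'
#' For every final candidate resolvable in the expression matrix and every
#' cancer type, evaluates both transitions (normal to primary, primary to
#' metastatic): fold change of cohort means, two-group Kruskal-Wallis
#' significance, and tier assignment via [stratify()]. A gene is a *hit*
#' when its primary-to-metastatic tier is high or medium. A transition with
#' an empty required cohort is skipped with a warning. A
#' Benjamini-Hochberg adjusted p-value column is emitted for information
#' only; tier assignment uses the raw p-values.
#'
#' @param cands a `candidate_table` (only rows with status `"final"` are
#'   tested).
#' @param study an [expression_study()]; cohorts are built on the fly if
#'   absent.
#' @param eps pseudocount forwarded to [fold_change()].
#' @param mode staging mode if cohorts need building.
#' @return A `hit_table` data frame: `gene`, `cancer_type`, `transition`,
#'   `fc`, `log2fc`, `h_stat`, `p_value`, `p_adj`, `tier`, `is_hit`.
#' @export
call_hits <- function(cands, study, eps = 1e-3, mode = "strict") {
  stopifnot(inherits(cands, "candidate_table"), inherits(study, "expression_study"))
  if (is.null(study$cohorts)) study <- build_cohorts(study, mode = mode)
  finals <- cands$symbol[cands$status == "final"]
  absent <- setdiff(finals, rownames(study$matrix))
  if (length(absent) > 0) {
    message(length(absent), " final candidate(s) absent from the expression matrix; skipped")
  }
  genes <- intersect(finals, rownames(study$matrix))
  transitions <- list(normal_primary = c("normal", "primary"),
                      primary_metastatic = c("primary", "metastatic"))
  rows <- list()
  for (ct in names(study$cohorts)) {
    co <- study$cohorts[[ct]]
    for (tr in names(transitions)) {
      from <- transitions[[tr]][1]; to <- transitions[[tr]][2]
      if (length(co[[from]]) == 0 || length(co[[to]]) == 0) {
        warning(ct, ": empty ", from, " or ", to, " cohort; ", tr,
                " transition skipped")
        next
      }
      for (gene in genes) {
        va <- study$matrix[gene, co[[from]]]
        vb <- study$matrix[gene, co[[to]]]
        fcr <- fold_change(va, vb, eps = eps)
        kw <- kruskal_wallis(list(va, vb))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, cancer_type = ct, transition = tr,
          fc = fcr$fc, log2fc = fcr$log2fc,
          h_stat = kw$h_stat, p_value = kw$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(gene = character(0), cancer_type = character(0),
                      transition = character(0), fc = numeric(0),
                      log2fc = numeric(0), h_stat = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      tier = character(0), is_hit = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::ave(out$p_value,
                          paste(out$cancer_type, out$transition),
                          FUN = function(p) stats::p.adjust(p, method = "BH"))
  out$tier <- stratify(out$log2fc, out$p_value)
  out$is_hit <- out$transition == "primary_metastatic" &
    out$tier %in% c("high", "medium")
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Read expression inputs from disk
#'
#' `read_expression_matrix()` expects a TSV whose first column holds gene
#' symbols and remaining columns FPKM values per sample;
#' `read_sample_metadata()` a TSV with columns `sample_id`, `cancer_type`,
#' `source`, `T`, `N`, `M`; `read_seed_list()` a plain-text file with one
#' gene symbol per line; `read_doid_map()` a TSV with columns `gene`,
#' `doid`, `term_name`, `slim`.
#'
#' @param path input file path.
#' @return Matrix, data frame, or character vector as appropriate.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_expression_matrix
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, colClasses = "character", quote = "")
  stopifnot(all(c("sample_id", "cancer_type", "source", "T", "N", "M") %in% names(md)))
  md
}

#' @rdname read_expression_matrix
#' @export
read_seed_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != ""]
}

#' @rdname read_expression_matrix
#' @export
read_doid_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  stopifnot(all(c("gene", "doid", "term_name", "slim") %in% names(df)))
  df
}
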
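#' Required summary-statistics columns
#'
#' Standard column names for tab-delimited summary statistics consumed by
#' [read_sumstats()]: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`. Exposure files carry
#' two further columns, `gene` and `cell_type`.
#'
#' @format Character vector of column names.
#' @export
sumstats_columns <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

ALLELE_RE <- "^[ACGT]+$"

#' Construct an exposure dataset
#'
#' Bundles the cis-association table of one gene in one cell type. The
#' association table must satisfy the per-row invariants enforced by
#' [read_sumstats()] (positive SEs, p-values in (0, 1], distinct A/C/G/T
#' alleles, unique variant ids).
#'
#' @param gene Gene symbol (eGene).
#' @param cell_type Cell-type label.
#' @param associations Data frame with the columns in [sumstats_columns].
#' @param cell_types Optional label set `cell_type` must belong to.
#' @return An object of class `exposure_dataset`.
#' @export
exposure_dataset <- function(gene, cell_type, associations, cell_types = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L,
            is.character(cell_type), length(cell_type) == 1L)
  if (!is.null(cell_types) && !cell_type %in% cell_types) {
    stop(sprintf("cell_type '%s' not among configured labels", cell_type),
         call. = FALSE)
  }
  associations <- tibble::as_tibble(associations)
  missing_cols <- setdiff(sumstats_columns, names(associations))
  if (length(missing_cols) > 0L) {
    stop("associations missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(associations) < 1L) {
    stop("an exposure dataset needs at least one association", call. = FALSE)
  }
  bad <- validate_association_rows(associations)
  if (nrow(bad) > 0L) {
    stop("invalid association rows: ",
         paste(sprintf("%s (%s)", bad$variant_id, bad$reason), collapse = "; "),
         call. = FALSE)
  }
  structure(
    list(gene = gene, cell_type = cell_type, associations = associations),
    class = "exposure_dataset"
  )
}

#' @export
print.exposure_dataset <- function(x, ...) {
  cat(sprintf("<exposure_dataset> %s / %s: %d cis association(s)\n",
              x$gene, x$cell_type, nrow(x$associations)))
  invisible(x)
}

# Row-level invariant checks shared by read_sumstats() and constructors.
# Returns a data frame (row, variant_id, reason); empty when all rows pass.
validate_association_rows <- function(df) {
  reasons <- character(0); rows <- integer(0); ids <- character(0)
  flag <- function(i, reason) {
    rows <<- c(rows, i)
    ids <<- c(ids, as.character(df$variant_id[i]))
    reasons <<- c(reasons, reason)
  }
  for (i in seq_len(nrow(df))) {
    se <- df$se[i]; p <- df$pvalue[i]
    ea <- toupper(as.character(df$effect_allele[i]))
    oa <- toupper(as.character(df$other_allele[i]))
    eaf <- df$eaf[i]; n <- df$n[i]
    if (is.na(se) || se <= 0) flag(i, "nonpositive SE")
    if (is.na(p) || p <= 0 || p > 1) flag(i, "p-value outside (0,1]")
    if (is.na(df$beta[i]) || !is.finite(df$beta[i])) flag(i, "non-finite beta")
    if (is.na(ea) || is.na(oa) || !grepl(ALLELE_RE, ea) ||
        !grepl(ALLELE_RE, oa)) {
      flag(i, "invalid alleles")
    } else if (ea == oa) flag(i, "identical alleles")
    if (!is.na(eaf) && (eaf < 0 || eaf > 1)) flag(i, "eaf outside [0,1]")
    if (is.na(n) || n < 2) flag(i, "sample size below 2")
  }
  dup <- duplicated(df$variant_id)
  for (i in which(dup)) flag(i, "duplicate variant_id")
  data.frame(row = rows, variant_id = ids, reason = reasons,
             stringsAsFactors = FALSE)
}

#' Read summary statistics
#'
#' Reads a tab-delimited (optionally gzip-compressed) summary-statistics file
#' and validates every row against the type invariants: `se > 0`,
#' `0 < pvalue <= 1`, distinct A/C/G/T alleles, `eaf` in `[0, 1]` or missing,
#' `n >= 2`, and unique variant ids within a dataset. Failing rows are
#' collected and reported together with their file line numbers.
#'
#' @param path Path to the file. A header naming the required columns is
#'   mandatory; `col_map` remaps non-standard headers.
#' @param role `"exposure"` (file also carries `gene` and `cell_type`
#'   columns; the table is split into one [exposure_dataset()] per
#'   gene-by-cell-type block) or `"outcome"` (a single association table).
#' @param col_map Optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(variant_id = "SNP", pvalue = "P")`.
#' @param cell_types Optional configured cell-type label set; exposure rows
#'   with labels outside it are a validation error.
#' @return For `role = "exposure"`, a named list of `exposure_dataset`
#'   objects (names `gene|cell_type`); for `role = "outcome"`, a tibble.
#' @export
read_sumstats <- function(path, role = c("exposure", "outcome"),
                          col_map = NULL, cell_types = NULL) {
  role <- match.arg(role)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      idx <- match(col_map[[std]], names(df))
      if (!is.na(idx)) names(df)[idx] <- std
    }
  }
  required <- sumstats_columns
  if (role == "exposure") required <- c("gene", "cell_type", required)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("format error in '%s': missing required column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[required]
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$chrom <- as.character(df$chrom)
  df$variant_id <- as.character(df$variant_id)

  collect_bad <- function(sub, offset) {
    bad <- validate_association_rows(sub)
    if (nrow(bad) > 0L) bad$row <- bad$row + offset  # file line numbers
    bad
  }
  if (role == "outcome") {
    bad <- collect_bad(df, 1L)  # +1 for the header line
  } else {
    # duplicate ids are judged within each gene x cell_type dataset
    key <- paste(df$gene, df$cell_type, sep = "|")
    bad_list <- lapply(split(seq_len(nrow(df)), key), function(idx) {
      b <- validate_association_rows(df[idx, , drop = FALSE])
      if (nrow(b) > 0L) b$row <- idx[b$row] + 1L
      b
    })
    bad <- do.call(rbind, bad_list)
    if (!is.null(cell_types)) {
      out <- which(!df$cell_type %in% cell_types)
      if (length(out) > 0L) {
        bad <- rbind(bad, data.frame(row = out + 1L,
                                     variant_id = df$variant_id[out],
                                     reason = "unknown cell_type",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(bad) && nrow(bad) > 0L) {
    bad <- bad[order(bad$row), , drop = FALSE]
    msg <- paste(sprintf("line %d [%s]: %s", bad$row, bad$variant_id,
                         bad$reason), collapse = "\n  ")
    stop(sprintf("validation errors in '%s' (%d row[s]):\n  %s",
                 path, nrow(bad), msg), call. = FALSE)
  }
  if (role == "outcome") return(tibble::as_tibble(df))
  key <- paste(df$gene, df$cell_type, sep = "|")
  out <- lapply(split(df, key), function(sub) {
    exposure_dataset(sub$gene[1L], sub$cell_type[1L],
                     sub[sumstats_columns], cell_types = cell_types)
  })
  out[unique(key)]
}

#' Write summary statistics
#'
#' Writes an association table, an [exposure_dataset()], or a list of
#' exposure datasets as tab-delimited text. Numeric columns are written with
#' 6 significant digits; a `.gz` suffix triggers gzip compression.
#'
#' @param x Outcome tibble, `exposure_dataset`, or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  if (inherits(x, "exposure_dataset")) x <- list(x)
  if (is.list(x) && length(x) > 0L && inherits(x[[1L]], "exposure_dataset")) {
    x <- do.call(rbind, lapply(x, function(d) {
      cbind(gene = d$gene, cell_type = d$cell_type,
            as.data.frame(d$associations))
    }))
  }
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1L)) & !names(x) %in% c("pos", "n")
  x[num] <- lapply(x[num], signif, digits = 6L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
  (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

complement_allele <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure effect allele, variant by
#' variant, using the standard two-sample MR convention: variants present in
#' both datasets are retained; when the outcome's effect/other alleles are
#' swapped (or strand-flipped) relative to the exposure, the outcome beta is
#' negated and its allele frequency replaced by `1 - eaf`; palindromic (A/T
#' or C/G) variants are dropped by default or, under `palindrome_policy =
#' "freq"`, oriented by allele frequency when both frequencies lie outside
#' `[0.5 - freq_tolerance, 0.5 + freq_tolerance]`; irreconcilable alleles
#' are dropped. Every exclusion is recorded with its reason.
#'
#' @param exposure An [exposure_dataset()].
#' @param outcome Outcome association table (tibble with the columns in
#'   [sumstats_columns]), keyed by `variant_id`.
#' @param palindrome_policy `"drop"` (default) or `"freq"`.
#' @param freq_tolerance Half-width of the ambiguous frequency band around
#'   0.5 used by the `"freq"` policy (default 0.08).
#' @param ld Optional square LD correlation matrix with variant ids as
#'   dimnames; subset to the retained variants.
#' @return A `harmonized_set`: list with `gene`, `cell_type`, a `data`
#'   tibble (per-variant exposure and outcome beta/se/p/eaf on a common
#'   effect allele), optional `ld`, sample sizes `n_exp`/`n_out`, and a
#'   `dropped` tibble of `(variant_id, reason)`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "freq"),
                      freq_tolerance = 0.08, ld = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "exposure_dataset"))
  exp_df <- as.data.frame(exposure$associations)
  out_df <- as.data.frame(outcome)
  shared <- intersect(exp_df$variant_id, out_df$variant_id)
  if (length(shared) == 0L) {
    stop("empty overlap: no variant_id shared between exposure and outcome",
         call. = FALSE)
  }
  exp_df <- exp_df[match(shared, exp_df$variant_id), , drop = FALSE]
  out_df <- out_df[match(shared, out_df$variant_id), , drop = FALSE]

  keep <- logical(length(shared))
  reason <- character(length(shared))
  beta_out <- out_df$beta; eaf_out <- out_df$eaf
  for (i in seq_along(shared)) {
    ea_x <- exp_df$effect_allele[i]; oa_x <- exp_df$other_allele[i]
    ea_y <- out_df$effect_allele[i]; oa_y <- out_df$other_allele[i]
    pal <- nchar(ea_x) == 1L && nchar(oa_x) == 1L && is_palindromic(ea_x, oa_x)
    direct <- (ea_y == ea_x && oa_y == oa_x) ||
      (!pal && complement_allele(ea_y) == ea_x &&
         complement_allele(oa_y) == oa_x)
    swapped <- (ea_y == oa_x && oa_y == ea_x) ||
      (!pal && complement_allele(ea_y) == oa_x &&
         complement_allele(oa_y) == ea_x)
    if (!direct && !swapped) { reason[i] <- "allele mismatch"; next }
    if (swapped) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    }
    if (pal) {
      if (palindrome_policy == "drop") {
        reason[i] <- "ambiguous palindrome"; next
      }
      f_x <- exp_df$eaf[i]; f_y <- eaf_out[i]
      band <- c(0.5 - freq_tolerance, 0.5 + freq_tolerance)
      if (is.na(f_x) || is.na(f_y) ||
          (f_x >= band[1L] && f_x <= band[2L]) ||
          (f_y >= band[1L] && f_y <= band[2L])) {
        reason[i] <- "ambiguous palindrome"; next
      }
      if ((f_x - 0.5) * (f_y - 0.5) < 0) {  # discordant: wrong strand
        beta_out[i] <- -beta_out[i]
        f_y <- 1 - f_y
      }
      eaf_out[i] <- f_y
    }
    keep[i] <- TRUE
  }

  data <- tibble::tibble(
    variant_id = shared[keep],
    effect_allele = exp_df$effect_allele[keep],
    other_allele = exp_df$other_allele[keep],
    beta_exp = exp_df$beta[keep], se_exp = exp_df$se[keep],
    pval_exp = exp_df$pvalue[keep], eaf_exp = exp_df$eaf[keep],
    beta_out = beta_out[keep], se_out = out_df$se[keep],
    pval_out = out_df$pvalue[keep], eaf_out = eaf_out[keep]
  )
  dropped <- tibble::tibble(variant_id = shared[!keep],
                            reason = reason[!keep])
  if (!is.null(ld)) {
    if (is.null(dimnames(ld))) {
      stop("ld matrix must carry variant ids as dimnames", call. = FALSE)
    }
    miss <- setdiff(data$variant_id, rownames(ld))
    if (length(miss) > 0L) {
      stop("ld matrix missing variants: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    ld <- ld[data$variant_id, data$variant_id, drop = FALSE]
  }
  structure(
    list(gene = exposure$gene, cell_type = exposure$cell_type,
         data = data, ld = ld,
         n_exp = if (nrow(data)) stats::median(exp_df$n[keep]) else NA_real_,
         n_out = if (nrow(data)) stats::median(out_df$n[keep]) else NA_real_,
         dropped = dropped),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s / %s: %d variant(s), %d dropped%s\n",
              x$gene, x$cell_type, nrow(x$data), nrow(x$dropped),
              if (!is.null(x$ld)) ", with LD" else ""))
  invisible(x)
}

#' Write a harmonized set and its exclusion audit
#'
#' Writes the per-variant harmonized table to `path` and, when any variant
#' was excluded, a companion `<path>.dropped.tsv` audit with one row per
#' exclusion reason.
#'
#' @param h A `harmonized_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  df <- cbind(gene = h$gene, cell_type = h$cell_type,
              as.data.frame(h$data))
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(h$dropped) > 0L) {
    utils::write.table(as.data.frame(h$dropped),
                       paste0(sub("\\.tsv$", "", path), ".dropped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
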
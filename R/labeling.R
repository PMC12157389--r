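# Construction of the conditioning variables. The batch (clutch) variable is
# isolated as the only label shared across clutches: every mutant gets a
# clutch-unique genotype code, controls are split into a shared-code group
# (the cross-clutch anchor) and clutch-unique "held-out" controls whose
# post-correction clustering later provides unsupervised evidence of batch
# removal.

#' Build per-sample condition codes
#'
#' Mutants receive a genotype code unique to their (genotype, clutch, age)
#' cell. Controls in each (clutch, age) cell are randomly partitioned: a
#' fraction `control_split_fraction` becomes held-out controls with a
#' clutch-unique code, the rest share one code per age group across all
#' clutches. Deterministic given `seed`; different seeds change only the
#' control split, never the mutant codes.
#'
#' @param labels data.frame with columns sample_id, genotype, clutch, age,
#'   control_flag.
#' @param control_split_fraction fraction of each clutch's controls assigned
#'   to the held-out group (default 0.5: one half shared, one half held out).
#' @param seed integer seed for the control split.
#' @return data.frame: the input columns plus genotype_code, clutch_code,
#'   age_code, heldout_control; attribute `lookup` maps each genotype_code
#'   back to (genotype, clutch, age, heldout).
#' @export
build_condition_codes <- function(labels, control_split_fraction = 0.5, seed = 1L) {
  need <- c("sample_id", "genotype", "clutch", "age", "control_flag")
  stopifnot(all(need %in% names(labels)))
  stopifnot(control_split_fraction >= 0, control_split_fraction < 1)
  for (cl in unique(labels$clutch)) {
    if (!any(labels$control_flag[labels$clutch == cl])) {
      stop("clutch '", cl, "' has no controls; the model cannot anchor it")
    }
  }
  out <- labels
  out$clutch_code <- out$clutch
  out$age_code <- out$age
  out$heldout_control <- FALSE
  out$genotype_code <- ifelse(
    out$control_flag,
    sprintf("ctrl|%s", out$age),
    sprintf("mut|%s|%s|%s", out$genotype, out$clutch, out$age))

  set.seed(seed)
  cells <- unique(out[out$control_flag, c("clutch", "age")])
  cells <- cells[order(cells$clutch, cells$age), , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    idx <- which(out$control_flag & out$clutch == cells$clutch[i] &
                   out$age == cells$age[i])
    n_ho <- floor(length(idx) * control_split_fraction)
    if (n_ho > 0) {
      ho <- sort(sample(idx, n_ho))
      out$heldout_control[ho] <- TRUE
      out$genotype_code[ho] <- sprintf("hoCtrl|%s|%s", cells$clutch[i], cells$age[i])
    }
  }
  lookup <- unique(out[, c("genotype_code", "genotype", "clutch", "age",
                           "heldout_control")])
  # the shared control code spans clutches: collapse its lookup rows
  shared <- grepl("^ctrl\\|", lookup$genotype_code)
  if (any(shared)) {
    lk_sh <- unique(lookup[shared, c("genotype_code", "genotype", "age",
                                     "heldout_control")])
    lk_sh$clutch <- NA_character_
    lookup <- rbind(lookup[!shared, ], lk_sh[, names(lookup)])
  }
  rownames(lookup) <- NULL
  attr(out, "lookup") <- lookup
  out
}

#' Stratified train/validation split
#'
#' Splits sample ids into train and validation sets, stratified by
#' genotype_code. Cells with a single sample go to train (with a warning);
#' a warning is also raised for cells smaller than 5.
#'
#' @param coded output of [build_condition_codes()].
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `val` character vectors of sample ids.
#' @export
split_train_val <- function(coded, fraction = 0.8, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  set.seed(seed)
  train <- character(0); val <- character(0)
  codes <- sort(unique(coded$genotype_code))
  small <- character(0); singleton <- character(0)
  for (cd in codes) {
    ids <- coded$sample_id[coded$genotype_code == cd]
    n <- length(ids)
    if (n < 5) small <- c(small, cd)
    if (n == 1) {
      singleton <- c(singleton, cd)
      train <- c(train, ids)
      next
    }
    n_tr <- max(1L, round(fraction * n))
    if (n_tr == n) n_tr <- n - 1L
    tr <- sort(sample(ids, n_tr))
    train <- c(train, tr)
    val <- c(val, setdiff(ids, tr))
  }
  if (length(singleton)) {
    warning("singleton condition cells assigned to train: ",
            paste(singleton, collapse = ", "))
  } else if (length(small)) {
    warning("condition cells with fewer than 5 samples: ",
            paste(small, collapse = ", "))
  }
  list(train = train, val = val)
}

#' Integer-index view of the condition codes
#'
#' Converts a coded label table into the integer index lists consumed by
#' the denoiser's embedding tables. By default the three factors stay
#' separate (factorized conditioning, which is what allows the clutch code
#' to be swapped at correction time while genotype and age are retained).
#' With `collapse = TRUE` every (genotype, clutch, age) code combination
#' becomes one collapsed code instead — a single unique encoding per
#' combination; note that a collapsed model cannot swap the clutch alone.
#'
#' @param coded output of [build_condition_codes()].
#' @param levels optional level sets from a previous call (for scoring new
#'   samples against a trained model).
#' @param collapse use one collapsed code per combination instead of the
#'   factorized triple.
#' @return object of class `condition_index` with integer vectors
#'   `genotype`, `clutch`, `age` and the `levels` used.
#' @export
condition_index <- function(coded, levels = NULL, collapse = FALSE) {
  if (collapse) {
    combo <- paste(coded$genotype_code, coded$clutch_code, coded$age_code,
                   sep = "<>")
    if (is.null(levels)) {
      levels <- list(genotype = sort(unique(combo)), clutch = "collapsed",
                     age = "collapsed")
    }
    gi <- match(combo, levels$genotype)
    if (anyNA(gi)) stop("unknown condition code")
    return(structure(list(genotype = gi, clutch = rep(1L, nrow(coded)),
                          age = rep(1L, nrow(coded)), levels = levels),
                     class = "condition_index"))
  }
  if (is.null(levels)) {
    levels <- list(genotype = sort(unique(coded$genotype_code)),
                   clutch = sort(unique(coded$clutch_code)),
                   age = sort(unique(coded$age_code)))
  }
  gi <- match(coded$genotype_code, levels$genotype)
  ci <- match(coded$clutch_code, levels$clutch)
  ai <- match(coded$age_code, levels$age)
  if (anyNA(gi) || anyNA(ci) || anyNA(ai)) stop("unknown condition code")
  structure(list(genotype = gi, clutch = ci, age = ai, levels = levels),
            class = "condition_index")
}
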
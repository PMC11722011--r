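#' Kabsch superposition of two structure models
#'
#' Least-squares rigid-body superposition of the selected atoms of `b`
#' onto `a` via the Kabsch SVD algorithm, with the proper-rotation
#' correction (determinant +1, no reflection). The RMSD is computed over
#' the same selection after superposition.
#'
#' @param a,b `structure_model` objects (see [read_pdb_models()]).
#' @param residues integer vector of residue numbers to select (default:
#'   all residues common to both models).
#' @param atoms atom name(s) to select (default `"CA"`).
#' @return List with `rmsd` (angstrom), `rotation` (3x3), `translation`
#'   (length 3; the superposed coordinates are `b %*% t(R) + t`),
#'   `n_atoms`, `residues`.
#' @export
kabsch_superpose <- function(a, b, residues = NULL, atoms = "CA") {
  xa <- select_coords(a, residues, atoms)
  xb <- select_coords(b, residues, atoms)
  key <- intersect(rownames(xa), rownames(xb))
  if (length(key) < 3)
    stop("need at least 3 common selected atoms (got ", length(key), ")")
  xa <- xa[key, , drop = FALSE]
  xb <- xb[key, , drop = FALSE]
  ca <- colMeans(xa); cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca); yb <- sweep(xb, 2, cb)
  h <- crossprod(yb, ya)           # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  yb_rot <- yb %*% t(rot)
  rmsd <- sqrt(mean(rowSums((yb_rot - ya)^2)))
  list(rmsd = rmsd, rotation = rot,
       translation = as.numeric(ca - cb %*% t(rot)),
       n_atoms = length(key),
       residues = as.integer(sub(":.*", "", key)))
}

select_coords <- function(model, residues, atoms) {
  stopifnot(inherits(model, "structure_model"))
  sel <- model$atom %in% atoms
  if (!is.null(residues)) sel <- sel & model$residue %in% residues
  m <- model[sel, , drop = FALSE]
  m <- m[order(m$residue, match(m$atom, atoms)), , drop = FALSE]
  key <- paste0(m$residue, ":", m$atom)
  if (anyDuplicated(key))
    stop("selection is ambiguous: duplicated residue/atom pairs")
  out <- as.matrix(m[, c("x", "y", "z")])
  rownames(out) <- key
  out
}

#' Per-model RMSD of an ensemble against a reference
#'
#' Each ensemble member is independently superposed on the reference over
#' the selection and its RMSD reported.
#'
#' @param ensemble list of `structure_model` objects.
#' @param reference a `structure_model`.
#' @inheritParams kabsch_superpose
#' @return List with `rmsd` (per-model vector), `mean`, `sd`.
#' @export
ensemble_rmsd <- function(ensemble, reference, residues = NULL,
                          atoms = "CA") {
  if (!length(ensemble)) stop("empty ensemble")
  r <- vapply(ensemble, function(m)
    kabsch_superpose(reference, m, residues, atoms)$rmsd, numeric(1))
  list(rmsd = r, mean = mean(r),
       sd = if (length(r) > 1) stats::sd(r) else NA_real_)
}

#' Free-vs-bound RMSD over a grid of model and range choices
#'
#' Deposited NMR ensembles rarely state which member and residue range a
#' printed RMSD refers to, so this helper scans model choices (first
#' model of each file, or explicit indices) against residue ranges and
#' reports the Cα RMSD for each combination.
#'
#' @param free_models,bound_models lists of `structure_model` objects.
#' @param ranges list of integer vectors, each a residue selection.
#' @param model_indices integer vector of model indices to try (default
#'   just the first model of each ensemble).
#' @return Data frame: `model_free`, `model_bound`, `range`, `n_atoms`,
#'   `rmsd`.
#' @export
rmsd_grid <- function(free_models, bound_models,
                      ranges = list(`1-81` = 1:81, `2-72` = 2:72),
                      model_indices = 1L) {
  combos <- expand.grid(mf = model_indices, mb = model_indices,
                        ri = seq_along(ranges))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mf <- combos$mf[i]; mb <- combos$mb[i]; ri <- combos$ri[i]
    fit <- kabsch_superpose(free_models[[mf]], bound_models[[mb]],
                            residues = ranges[[ri]], atoms = "CA")
    data.frame(model_free = mf, model_bound = mb,
               range = names(ranges)[ri] %||% paste0("range", ri),
               n_atoms = fit$n_atoms, rmsd = fit$rmsd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
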
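#' Construct a V(D)J recombination generative model
#'
#' The model is an explicit probabilistic recipe for a TCRbeta CDR3:
#' draw V, D and J segments from categorical weights; delete a
#' truncated-geometric number of nucleotides at each junction-facing end
#' (independent ends, capped by the available nucleotides and
#' `max_deletion`, renormalized over the truncated support); insert a
#' non-template nucleotide run at each junction whose length is 0 with
#' probability `pi0` (the TdT-activity dial) and otherwise follows a
#' shifted geometric with parameter `ins_p`; inserted bases are drawn
#' i.i.d. from `nt_comp`. With probability `d_skip_prob` the D segment is
#' skipped entirely and the single V-J junction carries one insert run
#' (recorded as the VD insert). Clone sizes in simulated repertoires are
#' log-normal with dispersion `clone_size_sigma`.
#'
#' @param library A `segment_library`.
#' @param v_weights,d_weights,j_weights Named probability vectors over
#'   the library's segment names; uniform when `NULL`.
#' @param q Per-end deletion geometric parameter in (0,1); larger means
#'   more trimming (P(k) proportional to q^k).
#' @param max_deletion Maximum deletions per end (nucleotides).
#' @param pi0 Probability in [0,1] that an insert run has length zero.
#' @param ins_p Shifted-geometric parameter in (0,1) for run length >= 1
#'   (mean run length 1/ins_p).
#' @param nt_comp Named A/C/G/T probabilities for inserted bases.
#' @param clone_size_sigma Log-normal sd of clone weights (>= 0).
#' @param d_skip_prob Probability of a D-less rearrangement in [0,1).
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(library, v_weights = NULL, d_weights = NULL,
                             j_weights = NULL, q = 0.4, max_deletion = 6,
                             pi0 = 0.15, ins_p = 0.3,
                             nt_comp = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2),
                             clone_size_sigma = 1, d_skip_prob = 0) {
  stopifnot(inherits(library, "segment_library"))
  uw <- function(n, nm) stats::setNames(rep(1 / n, n), nm)
  if (is.null(v_weights)) v_weights <- uw(nrow(library$v), library$v$name)
  if (is.null(d_weights)) d_weights <- uw(nrow(library$d), library$d$name)
  if (is.null(j_weights)) j_weights <- uw(nrow(library$j), library$j$name)
  .check_prob_vec(v_weights, library$v$name, "v_weights")
  .check_prob_vec(d_weights, library$d$name, "d_weights")
  .check_prob_vec(j_weights, library$j$name, "j_weights")
  .check_prob_vec(nt_comp, c("A", "C", "G", "T"), "nt_comp")
  .check_range(q, 0, 1, "q", open = TRUE)
  .check_range(ins_p, 0, 1, "ins_p", open = TRUE)
  .check_range(pi0, 0, 1, "pi0")
  .check_range(d_skip_prob, 0, 1, "d_skip_prob")
  if (max_deletion < 0 || max_deletion != round(max_deletion)) {
    stop("parameter out of range: max_deletion must be a non-negative ",
         "integer", call. = FALSE)
  }
  if (clone_size_sigma < 0) {
    stop("parameter out of range: clone_size_sigma must be >= 0",
         call. = FALSE)
  }
  structure(list(
    library = library,
    v_weights = v_weights[library$v$name],
    d_weights = d_weights[library$d$name],
    j_weights = j_weights[library$j$name],
    q = q, max_deletion = as.integer(max_deletion),
    pi0 = pi0, ins_p = ins_p,
    nt_comp = nt_comp[c("A", "C", "G", "T")],
    clone_size_sigma = clone_size_sigma,
    d_skip_prob = d_skip_prob), class = "generative_model")
}

.check_prob_vec <- function(p, names_needed, what) {
  if (is.null(names(p)) || !setequal(names(p), names_needed)) {
    stop("parameter out of range: ", what, " must be named over {",
         paste(names_needed, collapse = ", "), "}", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("parameter out of range: ", what,
         " must be non-negative and sum to 1", call. = FALSE)
  }
}

.check_range <- function(x, lo, hi, what, open = FALSE) {
  bad <- if (open) (x <= lo || x >= hi) else (x < lo || x > hi)
  if (length(x) != 1L || is.na(x) || bad) {
    stop("parameter out of range: ", what, " must be in ",
         if (open) "(" else "[", lo, ", ", hi,
         if (open) ")" else "]", call. = FALSE)
  }
}

#' @export
print.generative_model <- function(x, ...) {
  cat("V(D)J recombination model over ", nrow(x$library$v), " V / ",
      nrow(x$library$d), " D / ", nrow(x$library$j), " J segments\n",
      "  zero-insert prob pi0 = ", x$pi0,
      ", insertion geometric p = ", x$ins_p, "\n",
      "  deletion q = ", x$q, " (max ", x$max_deletion, "/end)",
      ", D-skip prob = ", x$d_skip_prob, "\n",
      "  clone-size log-normal sigma = ", x$clone_size_sigma, "\n",
      sep = "")
  invisible(x)
}

# Preset TdT-activity profiles. pi0 encodes the ontogenic gradient:
# limited TdT activity in early gestation gives the largest zero-insert
# probability, adult repertoires the smallest. Values are this package's
# documented defaults, not measured quantities.
.age_presets <- list(
  preterm_like = list(pi0 = 0.45),
  term_like    = list(pi0 = 0.15),
  adult_like   = list(pi0 = 0.05)
)

#' Build a preset generative model for an age-like profile
#'
#' Presets differ only in the zero-insertion probability `pi0`
#' (preterm_like 0.45 > term_like 0.15 > adult_like 0.05), modelling the
#' TdT-activity gradient from early gestation to adulthood; all other
#' parameters take the package defaults (`q = 0.4`, `max_deletion = 6`,
#' `ins_p = 0.3`, uniform segment weights, `clone_size_sigma = 1`).
#' Any field of [generative_model()] can be overridden.
#'
#' @param library A `segment_library`.
#' @param age_profile `"preterm_like"`, `"term_like"` or `"adult_like"`.
#' @param overrides Named list of parameter overrides.
#' @return A `generative_model`.
#' @examples
#' lib <- synthetic_segment_library()
#' m <- build_preset_model(lib, "preterm_like")
#' m$pi0 > build_preset_model(lib, "adult_like")$pi0
#' @export
build_preset_model <- function(library,
    age_profile = c("preterm_like", "term_like", "adult_like"),
    overrides = list()) {
  age_profile <- match.arg(age_profile)
  args <- .age_presets[[age_profile]]
  ok <- setdiff(names(formals(generative_model)), "library")
  bad <- setdiff(names(overrides), ok)
  if (length(bad)) {
    stop("unknown model parameter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args[names(overrides)] <- overrides
  do.call(generative_model, c(list(library = library), args))
}

#' Serialize / restore a generative model (YAML)
#'
#' The segment library travels with the model so a file fully specifies
#' the generative process.
#'
#' @param model A `generative_model`.
#' @param path File path.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  lib <- model$library
  obj <- list(
    v_weights = as.list(model$v_weights),
    d_weights = as.list(model$d_weights),
    j_weights = as.list(model$j_weights),
    q = model$q, max_deletion = model$max_deletion, pi0 = model$pi0,
    ins_p = model$ins_p, nt_comp = as.list(model$nt_comp),
    clone_size_sigma = model$clone_size_sigma,
    d_skip_prob = model$d_skip_prob,
    library = list(
      v = lapply(seq_len(nrow(lib$v)), function(i) as.list(
        lib$v[i, c("name", "cdr1_aa", "cdr2_aa", "nt_3prime")])),
      d = lapply(seq_len(nrow(lib$d)), function(i) as.list(
        lib$d[i, c("name", "nt")])),
      j = lapply(seq_len(nrow(lib$j)), function(i) as.list(
        lib$j[i, c("name", "nt", "anchor_offset")]))))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  bind <- function(lst) do.call(rbind, lapply(lst, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  lib <- segment_library(v = bind(obj$library$v), d = bind(obj$library$d),
                         j = bind(obj$library$j))
  generative_model(lib,
    v_weights = unlist(obj$v_weights), d_weights = unlist(obj$d_weights),
    j_weights = unlist(obj$j_weights), q = obj$q,
    max_deletion = obj$max_deletion, pi0 = obj$pi0, ins_p = obj$ins_p,
    nt_comp = unlist(obj$nt_comp),
    clone_size_sigma = obj$clone_size_sigma,
    d_skip_prob = obj$d_skip_prob)
}
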
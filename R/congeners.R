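# Congener registry: the 12 dioxin-like congeners (4 non-ortho + 8 mono-ortho)
# and the 6 non-dioxin-like indicator congeners. The three sets are disjoint.

.NON_ORTHO <- c(77L, 81L, 126L, 169L)
.MONO_ORTHO <- c(105L, 114L, 118L, 123L, 156L, 157L, 167L, 189L)
.NDL_INDICATOR <- c(28L, 52L, 101L, 138L, 153L, 180L)

#' PCB congener registry
#'
#' The congeners tracked by this package, identified by IUPAC number and
#' assigned to one of three disjoint groups: the four non-ortho dioxin-like
#' congeners (77, 81, 126, 169), the eight mono-ortho dioxin-like congeners
#' (105, 114, 118, 123, 156, 157, 167, 189), and the six non-dioxin-like
#' (ndl) indicator congeners (28, 52, 101, 138, 153, 180) summed for
#' regulatory purposes.
#'
#' @return A data frame with columns `congener` (integer IUPAC number) and
#'   `group` (one of `"non_ortho"`, `"mono_ortho"`, `"ndl_indicator"`).
#' @export
#' @examples
#' congener_registry()
congener_registry <- function() {
  data.frame(
    congener = c(.NON_ORTHO, .MONO_ORTHO, .NDL_INDICATOR),
    group = rep(c("non_ortho", "mono_ortho", "ndl_indicator"),
                c(length(.NON_ORTHO), length(.MONO_ORTHO), length(.NDL_INDICATOR)))
  )
}

#' @rdname congener_registry
#' @export
non_ortho_congeners <- function() .NON_ORTHO

#' @rdname congener_registry
#' @export
mono_ortho_congeners <- function() .MONO_ORTHO

#' @rdname congener_registry
#' @export
ndl_congeners <- function() .NDL_INDICATOR

#' @rdname congener_registry
#' @export
dl_congeners <- function() c(.NON_ORTHO, .MONO_ORTHO)

#' Group membership of congeners
#'
#' @param congener integer vector of IUPAC numbers.
#' @return Character vector of group names, one per input.
#' @export
congener_group <- function(congener) {
  reg <- congener_registry()
  idx <- match(as.integer(congener), reg$congener)
  if (anyNA(idx)) {
    stop("unknown congener(s): ",
         paste(congener[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  reg$group[idx]
}

#' Toxic equivalency factor (TEF) schemes
#'
#' A TEF scheme maps each dioxin-like congener to its potency relative to
#' 2,3,7,8-TCDD. The default `"who2005"` scheme carries the WHO 2005 values
#' used for PCBs in milk-monitoring work: 77 -> 0.0001, 81 -> 0.0003,
#' 126 -> 0.1, 169 -> 0.03, and all eight mono-ortho congeners -> 0.00003.
#' ndl indicator congeners carry no TEF. Schemes are data, not code: pass a
#' named numeric vector via `tef` to define a custom scheme.
#'
#' @param name scheme identifier; `"who2005"` is built in.
#' @param tef optional named numeric vector (names = IUPAC numbers) defining
#'   a custom scheme; must cover all 12 dl congeners with factors >= 0.
#' @return An object of class `tef_scheme` with elements `name` and `tef`.
#' @export
#' @examples
#' s <- tef_scheme()
#' s$tef[["126"]]
tef_scheme <- function(name = "who2005", tef = NULL) {
  if (is.null(tef)) {
    if (!identical(name, "who2005")) {
      stop("unknown built-in TEF scheme: ", name, call. = FALSE)
    }
    tef <- c(`77` = 1e-4, `81` = 3e-4, `126` = 0.1, `169` = 0.03,
             `105` = 3e-5, `114` = 3e-5, `118` = 3e-5, `123` = 3e-5,
             `156` = 3e-5, `157` = 3e-5, `167` = 3e-5, `189` = 3e-5)
  }
  ids <- as.integer(names(tef))
  if (anyNA(ids)) stop("TEF names must be IUPAC numbers", call. = FALSE)
  grp <- congener_group(ids)  # errors on unknown congeners
  if (any(grp == "ndl_indicator")) {
    stop("ndl indicator congeners carry no TEF: ",
         paste(ids[grp == "ndl_indicator"], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(dl_congeners(), ids)
  if (length(missing)) {
    stop("TEF scheme must cover every dl congener; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tef < 0)) stop("TEF factors must be >= 0", call. = FALSE)
  structure(list(name = name, tef = tef), class = "tef_scheme")
}

#' @export
print.tef_scheme <- function(x, ...) {
  cat("TEF scheme '", x$name, "' (", length(x$tef), " congeners)\n", sep = "")
  print(x$tef)
  invisible(x)
}

#' Look up the TEF of a congener in a scheme
#'
#' @param scheme a [tef_scheme()].
#' @param congener integer vector of IUPAC numbers.
#' @return Numeric vector of factors.
#' @export
tef_for <- function(scheme, congener) {
  stopifnot(inherits(scheme, "tef_scheme"))
  idx <- match(as.character(as.integer(congener)), names(scheme$tef))
  if (anyNA(idx)) {
    stop("congener(s) not in TEF scheme '", scheme$name, "': ",
         paste(congener[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  unname(scheme$tef[idx])
}
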
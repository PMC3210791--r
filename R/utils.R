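#' Logit and inverse-logit transforms
#'
#' `logit()` maps a probability to the log-odds scale,
#' `inv_logit()` maps back. Probabilities must lie strictly inside (0, 1);
#' use [clip_prob()] first for values that may sit on the boundary.
#'
#' @param p Numeric vector of probabilities in (0, 1).
#' @param x Numeric vector of log-odds.
#' @return Numeric vector.
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.3))
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1); ",
         "clip boundary values with clip_prob() first", call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clip probabilities away from 0 and 1
#'
#' External tools sometimes round predicted probabilities to exactly 0 or 1,
#' which breaks the logit transform. Values are clipped into
#' `[eps, 1 - eps]` before any log-odds computation.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param eps Clipping margin, default `1e-6`.
#' @return Numeric vector in `[eps, 1 - eps]`.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Nottingham Prognostic Index
#'
#' Classical breast-cancer prognostic score combining histological grade,
#' nodal involvement and tumour size:
#' `NPI = grade + node score + 0.2 * size`, with size expressed in
#' centimetres (the original Nottingham convention). This function takes
#' the size in millimetres, as usually recorded, and converts.
#'
#' @param grade Histological (Elston-Ellis) grade, 1, 2 or 3.
#' @param nodes Nodal category score (1 = node negative, 2 = 1-3 nodes,
#'   3 = 4 or more nodes).
#' @param size_mm Invasive tumour size in millimetres (>= 0).
#' @return Numeric NPI value.
#' @examples
#' nottingham_prognostic_index(2, 1, 20) # 3.4
#' @export
nottingham_prognostic_index <- function(grade, nodes, size_mm) {
  if (any(!grade %in% c(1, 2, 3))) {
    stop("grade must be 1, 2 or 3", call. = FALSE)
  }
  if (any(!is.finite(size_mm)) || any(size_mm < 0)) {
    stop("size_mm must be a non-negative size in millimetres", call. = FALSE)
  }
  grade + nodes + 0.2 * (size_mm / 10)
}

# jsonlite writes named atomic vectors as plain arrays, dropping names;
# convert them to lists so config files round-trip level names.
.named_to_list <- function(x) {
  if (is.list(x)) return(lapply(x, .named_to_list))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. Keeps all simulation entry points free
# of global RNG side effects.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  force(code)
}
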
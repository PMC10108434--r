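#' Ionic strength of a salt mixture
#'
#' Computes `I = 1/2 * sum(c_i * z_i^2)` over all dissolved ionic species.
#' Rows may either name a recognised salt (expanded into its ions using the
#' built-in stoichiometry table) or supply an ion directly via the `charge`
#' column. Buffer components are only counted if they are listed, matching the
#' convention of reporting salt-only ionic strengths.
#'
#' @param salts A data frame with columns `species` (character) and `conc_M`
#'   (molar concentration of the salt or ion) and optionally `charge`
#'   (integer ion charge). Rows with a non-missing `charge` are treated as a
#'   single ionic species at that concentration; rows without a charge must
#'   name a salt known to [known_salts()].
#'
#' @return Ionic strength in molar units (single number).
#' @export
#' @examples
#' compute_ionic_strength(data.frame(species = "NaCl", conc_M = 0.8)) # 0.8
#' # 0.1 M NaCl + 0.05 M CaCl2 -> 0.25 M
#' compute_ionic_strength(data.frame(species = c("NaCl", "CaCl2"),
#'                                   conc_M = c(0.1, 0.05)))
compute_ionic_strength <- function(salts) {
  stopifnot(is.data.frame(salts))
  if (nrow(salts) == 0) return(0)
  if (!all(c("species", "conc_M") %in% names(salts))) {
    abort("`salts` needs columns `species` and `conc_M`.")
  }
  check_numeric_vec(salts$conc_M, "conc_M", lower = 0)
  if (!"charge" %in% names(salts)) salts$charge <- NA_real_
  tab <- known_salts()
  ions <- purrr::pmap(salts, function(species, conc_M, charge, ...) {
    if (!is.na(charge)) {
      return(tibble(conc_M = conc_M, charge = charge))
    }
    hit <- tab[tab$salt == species, ]
    if (nrow(hit) == 0) {
      abort(sprintf(
        "No charge given for species '%s' and it is not a recognised salt.",
        species
      ))
    }
    tibble(conc_M = conc_M * hit$stoich[[1]]$nu, charge = hit$stoich[[1]]$z)
  }) |> purrr::list_rbind()
  0.5 * sum(ions$conc_M * ions$charge^2)
}

#' Recognised simple salts and their ion stoichiometries
#'
#' @return A tibble with columns `salt` and `stoich` (list of data frames with
#'   per-ion stoichiometric number `nu` and charge `z`).
#' @export
known_salts <- function() {
  mk <- function(nu, z) data.frame(nu = nu, z = z)
  tibble(
    salt = c("NaCl", "KCl", "LiCl", "CaCl2", "MgCl2", "Na2SO4"),
    stoich = list(
      mk(c(1, 1), c(1, -1)),
      mk(c(1, 1), c(1, -1)),
      mk(c(1, 1), c(1, -1)),
      mk(c(1, 2), c(2, -1)),
      mk(c(1, 2), c(2, -1)),
      mk(c(2, 1), c(1, -2))
    )
  )
}
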
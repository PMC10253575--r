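#' Central pressure record
#'
#' @param central_SBP central systolic blood pressure, mmHg.
#' @param central_DBP central diastolic blood pressure, mmHg.
#' @return a `pressure_record` with the pulse pressure `PP = SBP - DBP`.
#' @export
pressure_record <- function(central_SBP, central_DBP) {
  assert_that(central_SBP > central_DBP && central_DBP > 0,
              "need SBP > DBP > 0")
  structure(list(central_SBP = central_SBP, central_DBP = central_DBP,
                 PP = central_SBP - central_DBP),
            class = "pressure_record")
}

#' Lumen area pair at one aortic site
#'
#' @param site "ascending" or "descending".
#' @param Amax systolic lumen area, mm^2.
#' @param Amin diastolic lumen area, mm^2 (0 < Amin <= Amax).
#' @return an `area_curve_set`.
#' @export
area_curve_set <- function(site, Amax, Amin) {
  site <- match.arg(site, c("ascending", "descending"))
  assert_that(Amin > 0 && Amax >= Amin, "need Amax >= Amin > 0")
  structure(list(site = site, Amax = Amax, Amin = Amin),
            class = "area_curve_set")
}

#' Generate lumen areas and pressure consistent with a subject's
#' distensibility
#'
#' Inverts the distensibility definition D = dA / (Amin * PP) as a
#' generative rule: given the subject's true distensibility (in
#' 1e-3/mmHg) and pulse pressure, the systolic-diastolic area change at
#' each site is dA = D * Amin * PP, so the analysis-side distensibility
#' recovers the ground truth exactly when both sites share it.
#'
#' @param subject a `subject_truth` row/list with `true_distensibility`
#'   (1e-3/mmHg) and a `pressure` [pressure_record()].
#' @param Amin_AA diastolic ascending-aorta area, mm^2.
#' @param Amin_DA diastolic descending-aorta area, mm^2.
#' @return list with `areas_AA`, `areas_DA` ([area_curve_set()]) and
#'   `pressure`.
#' @export
make_area_and_pressure <- function(subject, Amin_AA = 968, Amin_DA = 560) {
  assert_that(Amin_AA > 0 && Amin_DA > 0, "Amin values must be > 0")
  pr <- subject$pressure
  assert_that(inherits(pr, "pressure_record"), "subject$pressure invalid")
  D <- subject$true_distensibility * 1e-3          # 1/mmHg
  dA_AA <- D * Amin_AA * pr$PP
  dA_DA <- D * Amin_DA * pr$PP
  list(areas_AA = area_curve_set("ascending", Amin_AA + dA_AA, Amin_AA),
       areas_DA = area_curve_set("descending", Amin_DA + dA_DA, Amin_DA),
       pressure = pr)
}
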
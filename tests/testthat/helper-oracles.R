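# Independent oracles for the toy network and the LP solver.
#
# The closed forms below are derived by hand from the toy network's balance
# equations (acetyl-CoA, ATP, NADH, NADPH, O2), NOT by running the package's
# LP code.  Derivation sketch, with g = glucose uptake and o2 = oxygen
# uptake bound (mmol/gCDW/h):
#
#   biomass draws 2 accoa + 150 atp + 2 nadph per unit of growth mu.
#   oxidative route y (per glc): 2 accoa + 4 nadh + 2 atp
#   fermentative route z:        2 lactate + 2 atp (no NADH)
#   respiration r: 1 nadh + 0.5 o2 -> 2 atp;  transhydrogenase t: nadh -> nadph
#
#   O2 slack (r = 4g - 2mu <= 2*o2):  mu = g/13 from the ATP balance
#     12g - 14mu - ... => m = 12g - 156mu/ (with acetate slack a = 2g - 2mu)
#   O2 binding (r = 2*o2): y = o2/2 + mu/2, z = g - y, a = o2 - mu,
#     ATP balance => mu = (2g + 5*o2) / 151
#
# Max product flux p at mu = 0 (2 accoa + 1 nadph per monomer):
#   y = p, r = 3p <= 2*o2  =>  p = min(g, 2*o2/3)

toy_mu_max <- function(g, o2max = 15) {
  if (50 * g / 13 <= 2 * o2max) g / 13 else (2 * g + 5 * o2max) / 151
}

toy_max_phb <- function(g, o2max = 15) min(g, 2 * o2max / 3)

# biomass yield on glucose in the O2-unconstrained regime: 1/13 g per mmol,
# constant along the batch, so the batch has the closed form
#   X_final = X0 + C0 / 13     (C0 in mmol/L)
toy_batch_final_biomass <- function(X0, C0_mmol_l) X0 + C0_mmol_l / 13

# ---- scipy (HiGHS) LP oracle ---------------------------------------------

scipy_available <- function() nzchar(Sys.which("python"))

.scipy_script <- function() {
  path <- file.path(tempdir(), "lp_oracle.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import json, sys",
      "import numpy as np",
      "from scipy.optimize import linprog",
      "d = json.load(open(sys.argv[1]))",
      "c = np.asarray(d['c'], float)",
      "A = np.asarray(d['A'], float)",
      "lb = [None if x <= -1e29 else x for x in d['lb']]",
      "ub = [None if x >= 1e29 else x for x in d['ub']]",
      "s = -1.0 if d['max'] else 1.0",
      "r = linprog(s * c, A_eq=A, b_eq=np.zeros(A.shape[0]),",
      "            bounds=list(zip(lb, ub)), method='highs')",
      "status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'other')",
      "out = {'status': status,",
      "       'value': (s * r.fun) if r.status == 0 else None}",
      "json.dump(out, open(sys.argv[2], 'w'))"), path)
  }
  path
}

scipy_lp <- function(obj, A, lb, ub, maximize = TRUE) {
  fin <- function(x, repl) ifelse(is.finite(x), x, repl)
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    c = obj, A = A, lb = fin(lb, -1e30), ub = fin(ub, 1e30),
    max = maximize), digits = NA, auto_unbox = FALSE), inp)
  status <- system2("python", c(.scipy_script(), inp, outp),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("scipy oracle failed")
  jsonlite::fromJSON(outp)
}

# a toy model with the NADPH pathway, shared across tests
toy_phb <- function(cofactor = "NADPH") {
  add_phb_pathway(make_toy_model(), cofactor)
}

# fast-but-accurate batch setup for tests (shorter output grid than default)
test_setup <- function(...) {
  batch_setup(tracked_species = c("glucose", "phb", "acetate", "lactate",
                                  "co2"), ...)
}
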
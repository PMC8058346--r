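"""Batched LP/MILP solves via scipy's HiGHS interface.

Reads a JSON file {"problems": [...]} and writes a JSON list of results.
Each problem:
  sense        : "min" | "max"
  c            : objective coefficients
  A_eq / A_ub  : {"i": [...], "j": [...], "x": [...], "nrow": r, "ncol": c}
                 (1-based indices) or null
  b_eq / b_ub  : right-hand sides
  lb, ub       : variable bounds; |value| >= 1e29 means infinite
  integrality  : 0/1 per variable (1 = integer)
  time_limit   : seconds or null
Each result: {"status": str, "x": [...] | null, "objective": num | null}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import milp, Bounds, LinearConstraint

INF_SENTINEL = 1e29

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def _mat(spec):
    if spec is None:
        return None
    i = np.atleast_1d(np.asarray(spec["i"], dtype=int)) - 1
    j = np.atleast_1d(np.asarray(spec["j"], dtype=int)) - 1
    x = np.atleast_1d(np.asarray(spec["x"], dtype=float))
    if len(x) == 1:
        # single-entry triplets confuse the sparse constructor's shape
        # heuristics; a duplicate zero entry is summed away harmlessly
        i, j, x = np.r_[i, i], np.r_[j, j], np.r_[x, 0.0]
    return sparse.csc_matrix(
        (x, (i, j)), shape=(int(spec["nrow"]), int(spec["ncol"]))
    )


def _bounds(v, side):
    v = np.asarray(v, dtype=float)
    v[v >= INF_SENTINEL] = np.inf
    v[v <= -INF_SENTINEL] = -np.inf
    return v


def solve_one(p):
    c = np.asarray(p["c"], dtype=float)
    sign = -1.0 if p.get("sense", "min") == "max" else 1.0
    cons = []
    a_eq = _mat(p.get("A_eq"))
    if a_eq is not None and a_eq.shape[0] > 0:
        b = np.asarray(p["b_eq"], dtype=float)
        cons.append(LinearConstraint(a_eq, b, b))
    a_ub = _mat(p.get("A_ub"))
    if a_ub is not None and a_ub.shape[0] > 0:
        b = np.asarray(p["b_ub"], dtype=float)
        cons.append(LinearConstraint(a_ub, -np.inf, b))
    lb = _bounds(p["lb"], "lb")
    ub = _bounds(p["ub"], "ub")
    integrality = np.asarray(p.get("integrality") or np.zeros_like(c), dtype=int)
    opts = {}
    if p.get("time_limit") is not None:
        opts["time_limit"] = float(p["time_limit"])
    try:
        res = milp(
            sign * c,
            constraints=cons,
            integrality=integrality,
            bounds=Bounds(lb, ub),
            options=opts,
        )
    except Exception as exc:  # numerical failure, not infeasibility
        return {"status": "error", "message": str(exc), "x": None, "objective": None}
    status = STATUS.get(res.status, "error")
    if res.x is None:
        return {"status": status, "x": None, "objective": None}
    return {
        "status": status,
        "x": [float(v) for v in res.x],
        "objective": float(sign * res.fun),
    }


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    out = [solve_one(p) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
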
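"""Batch MILP worker: reads a JSON problem batch, solves each instance with
HiGHS (via scipy.optimize.milp) and writes a JSON list of solutions.

Usage: python milp_bridge.py <in.json> <out.json>

Infinite bounds are encoded as +/-1e30 in the JSON.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, Bounds, milp

INF_SENTINEL = 1e30

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def _arr(x, dtype=float):
    a = np.atleast_1d(np.asarray(x, dtype=dtype))
    return a


def _uncap(a):
    a = a.astype(float).copy()
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def solve_one(p, options):
    n = int(p["n_var"])
    c = _arr(p.get("obj", [0.0] * n))
    sense = -1.0 if p.get("maximize", False) else 1.0
    bounds = Bounds(_uncap(_arr(p["var_lb"])), _uncap(_arr(p["var_ub"])))
    integrality = _arr(p.get("integrality", [0] * n), dtype=int)
    constraints = []
    m = int(p.get("n_con", 0))
    if m > 0:
        i = _arr(p["A_i"], int) - 1
        j = _arr(p["A_j"], int) - 1
        v = _arr(p["A_v"])
        A = sparse.csc_matrix((v, (i, j)), shape=(m, n))
        constraints.append(LinearConstraint(A, _uncap(_arr(p["con_lb"])),
                                            _uncap(_arr(p["con_ub"]))))
    res = milp(sense * c, constraints=constraints, bounds=bounds,
               integrality=integrality, options=options)
    out = {"status": STATUS.get(res.status, "error")}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(sense * res.fun)
    else:
        out["x"] = None
        out["objective"] = None
    return out


def main(fin, fout):
    with open(fin) as fh:
        payload = json.load(fh)
    opts = payload.get("options", {}) or {}
    options = {"mip_rel_gap": float(opts.get("mip_rel_gap", 0.0)),
               "presolve": True, "disp": False}
    results = [solve_one(p, options) for p in payload.get("problems", [])]
    with open(fout, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
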
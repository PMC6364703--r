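"""Batched LP/MILP solving via scipy's HiGHS interface.

Reads a JSON problem file (argv[1]) and writes a JSON result file (argv[2]).

Input schema:
{
  "problems": [
    {
      "n": <int>,                      # number of variables
      "lb": [...], "ub": [...],        # variable bounds, length n
      "A":  {"i": [...], "j": [...], "x": [...]},   # 0-based triplets
      "row_lb": [...], "row_ub": [...],
      "integrality": [...],            # optional, 0/1 per variable
      "objectives": [
        {"sense": "max"|"min", "j": [...], "x": [...], "want_x": true|false}
      ]
    }, ...
  ]
}

Output schema:
{"results": [[{"status": str, "objective": num|null, "x": [...]|null}, ...], ...]}

Each problem is solved once per objective over the same feasible region, which
is how flux variability analysis batches its many min/max sub-problems into a
single process invocation.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

STATUS = {0: "optimal", 1: "failed", 2: "infeasible", 3: "unbounded", 4: "failed"}


def solve_problem(prob):
    n = int(prob["n"])
    lb = np.asarray(prob["lb"], dtype=float)
    ub = np.asarray(prob["ub"], dtype=float)
    lb[lb <= -1e30] = -np.inf
    ub[ub >= 1e30] = np.inf
    integrality = np.asarray(prob.get("integrality", [0] * n), dtype=int)

    a = prob.get("A") or {"i": [], "j": [], "x": []}
    m = len(prob.get("row_lb") or [])
    constraints = []
    if m:
        mat = sparse.csr_matrix(
            (np.asarray(a["x"], dtype=float),
             (np.asarray(a["i"], dtype=int), np.asarray(a["j"], dtype=int))),
            shape=(m, n),
        )
        row_lb = np.asarray(prob["row_lb"], dtype=float)
        row_ub = np.asarray(prob["row_ub"], dtype=float)
        row_lb[row_lb <= -1e30] = -np.inf
        row_ub[row_ub >= 1e30] = np.inf
        constraints = [LinearConstraint(mat, row_lb, row_ub)]

    out = []
    for objective in prob["objectives"]:
        c = np.zeros(n)
        if objective.get("j"):
            c[np.asarray(objective["j"], dtype=int)] = np.asarray(
                objective["x"], dtype=float
            )
        sign = -1.0 if objective.get("sense", "min") == "max" else 1.0
        res = milp(
            c=sign * c,
            constraints=constraints,
            integrality=integrality,
            bounds=Bounds(lb, ub),
        )
        status = STATUS.get(res.status, "failed")
        record = {"status": status, "objective": None, "x": None}
        if status == "optimal":
            record["objective"] = float(sign * res.fun)
            if objective.get("want_x", False):
                record["x"] = [float(v) for v in res.x]
        out.append(record)
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    results = [solve_problem(p) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main()
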
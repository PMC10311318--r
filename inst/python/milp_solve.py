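"""Batched binary-program worker.

Reads a JSON batch of minimization models over binary variables, solves each
with HiGHS (scipy.optimize.milp), optionally enumerating co-optimal
assignments by adding no-good cuts, and writes the solutions back as JSON.

Usage: python milp_solve.py input.json output.json
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix


def solve_one(prob, time_limit, obj_tol):
    nv = int(prob["nvars"])
    c = np.asarray(prob["obj"], dtype=float)
    ci = np.asarray(prob["con_i"], dtype=np.int64)
    cj = np.asarray(prob["con_j"], dtype=np.int64)
    cv = np.asarray(prob["con_v"], dtype=float)
    row_lb = np.atleast_1d(np.asarray(prob["row_lb"], dtype=float))
    row_ub = np.atleast_1d(np.asarray(prob["row_ub"], dtype=float))
    cut_vars = np.atleast_1d(np.asarray(prob["cut_vars"], dtype=np.int64))
    limit = int(prob.get("limit", 1))
    # probe: after hitting the limit, re-solve once more to learn whether
    # further optima exist (sets the truncated flag); plain solves skip it.
    probe = bool(prob.get("probe", False))
    nrow = row_lb.size

    rows = [ci]
    cols = [cj]
    vals = [cv]
    lbs = [row_lb]
    ubs = [row_ub]
    opts = {"time_limit": float(time_limit)}
    integrality = np.ones(nv)
    bounds = Bounds(0, 1)

    solutions = []
    best = None
    status = "unknown"
    truncated = False
    while True:
        A = csr_matrix(
            (np.concatenate(vals), (np.concatenate(rows), np.concatenate(cols))),
            shape=(nrow, nv),
        )
        res = milp(
            c,
            constraints=LinearConstraint(A, np.concatenate(lbs), np.concatenate(ubs)),
            integrality=integrality,
            bounds=bounds,
            options=opts,
        )
        if res.status == 2:  # infeasible: all optima already cut away
            status = "optimal" if solutions else "infeasible"
            break
        if res.status != 0:
            if solutions:
                status = "optimal"  # enumeration cut short by time limit
                truncated = True
            else:
                status = "time_limit" if res.status == 1 else "failed"
            break
        x = np.rint(res.x).astype(int)
        obj = float(c @ x)
        if best is None:
            best = obj
            status = "optimal"
        elif obj > best + obj_tol:
            break  # objective strictly worsened: enumeration complete
        if len(solutions) >= limit:
            truncated = True  # another optimum exists beyond the limit
            break
        solutions.append(x.tolist())
        if len(solutions) >= limit and not probe:
            break
        # no-good cut excluding this assignment on the cut variables:
        # sum_{x_k=1} (1 - x_k) + sum_{x_k=0} x_k >= 1
        ones = cut_vars[x[cut_vars] == 1]
        zeros = cut_vars[x[cut_vars] == 0]
        r = nrow
        nrow += 1
        idx = np.concatenate([ones, zeros])
        rows.append(np.full(idx.size, r, dtype=np.int64))
        cols.append(idx)
        vals.append(np.concatenate([-np.ones(ones.size), np.ones(zeros.size)]))
        lbs.append(np.array([1.0 - ones.size]))
        ubs.append(np.array([1e30]))
    return {
        "status": status,
        "objective": best,
        "solutions": solutions,
        "truncated": bool(truncated),
    }


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    time_limit = payload.get("time_limit", 600)
    obj_tol = payload.get("obj_tol", 1e-6)
    out = [solve_one(p, time_limit, obj_tol) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
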
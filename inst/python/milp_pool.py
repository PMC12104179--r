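"""Batch MILP solution-pool enumerator.

Reads a JSON file describing a batch of binary linear programs (sparse
constraint triplets, per-row bounds, all variables binary), solves each with
HiGHS through scipy.optimize.milp, and enumerates every alternate optimum via
no-good cuts over the first n_z (decision) variables:

    sum_{i in supp(z*)} (1 - z_i) + sum_{i not in supp(z*)} z_i >= 1

Enumeration stops when the incumbent objective exceeds the optimum by more
than `tol` (zero pool gap up to numerical tolerance) or when `cap` solutions
have been collected. Writes a JSON file with one result per problem.

Usage: python milp_pool.py in.json out.json
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def solve_pool(prob):
    n = int(prob["n_vars"])
    n_z = int(prob["n_z"])
    cap = int(prob["cap"])
    tol = float(prob["tol"])
    c = np.asarray(prob["obj"], dtype=float)
    ai = np.asarray(prob["ai"], dtype=int)
    aj = np.asarray(prob["aj"], dtype=int)
    ax = np.asarray(prob["ax"], dtype=float)
    n_rows = int(prob["n_rows"])
    row_lower = np.asarray(prob["row_lower"], dtype=float)
    row_upper = np.asarray(prob["row_upper"], dtype=float)
    row_lower[row_lower <= -INF] = -np.inf
    row_upper[row_upper >= INF] = np.inf

    cut_rows = []  # each: (indices, coeffs, lb)
    solutions = []
    objectives = []
    optimum = None
    capped = False
    bounds = Bounds(0.0, 1.0)
    integrality = np.ones(n)
    options = {"mip_rel_gap": 0.0, "presolve": True}

    while True:
        extra = len(cut_rows)
        if extra:
            ci = np.concatenate(
                [np.full(len(idx), n_rows + k) for k, (idx, _, _) in enumerate(cut_rows)]
            )
            cj = np.concatenate([idx for idx, _, _ in cut_rows])
            cx = np.concatenate([coef for _, coef, _ in cut_rows])
            A = sparse.coo_matrix(
                (np.concatenate([ax, cx]), (np.concatenate([ai, ci]), np.concatenate([aj, cj]))),
                shape=(n_rows + extra, n),
            )
            lb = np.concatenate([row_lower, [lbv for _, _, lbv in cut_rows]])
            ub = np.concatenate([row_upper, np.full(extra, np.inf)])
        else:
            A = sparse.coo_matrix((ax, (ai, aj)), shape=(n_rows, n))
            lb, ub = row_lower, row_upper

        res = milp(
            c,
            constraints=LinearConstraint(A.tocsc(), lb, ub),
            integrality=integrality,
            bounds=bounds,
            options=options,
        )
        if res.status != 0 or res.x is None:
            if optimum is None:
                return {"status": "infeasible"}
            break
        obj = float(c @ np.round(res.x))
        if optimum is None:
            optimum = obj
        elif obj > optimum + tol:
            break
        z = np.round(res.x[:n_z]).astype(int)
        supp = np.flatnonzero(z == 1)
        solutions.append(supp.tolist())
        objectives.append(obj)
        if len(solutions) >= cap:
            capped = True
            break
        idx = np.arange(n_z)
        coef = np.where(z == 1, -1.0, 1.0)
        cut_rows.append((idx, coef, 1.0 - float(supp.size)))

    return {
        "status": "optimal",
        "optimum": optimum,
        "solutions": solutions,
        "objectives": objectives,
        "capped": capped,
    }


def main(argv):
    with open(argv[1]) as fh:
        batch = json.load(fh)
    results = [solve_pool(p) for p in batch["problems"]]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv)
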
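"""Batch MILP bridge: read models from JSON, solve with HiGHS via
scipy.optimize.milp, write solutions to JSON.

Usage: python milp_highs.py <in.json> <out.json>
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csc_matrix

BIG = 1e29  # bounds at or beyond this magnitude are treated as infinite


def _inf(v):
    v = np.asarray(v, dtype=float)
    v = np.where(v >= BIG, np.inf, v)
    v = np.where(v <= -BIG, -np.inf, v)
    return v


def solve_one(m, options):
    n = int(m["n"])
    ncon = int(m["ncon"])
    c = np.asarray(m["obj"], dtype=float)
    integrality = np.asarray(m["integer"], dtype=int)
    bounds = Bounds(_inf(m["lb"]), _inf(m["ub"]))
    constraints = []
    if ncon > 0:
        A = csc_matrix(
            (np.asarray(m["ax"], dtype=float),
             (np.asarray(m["ai"], dtype=int), np.asarray(m["aj"], dtype=int))),
            shape=(ncon, n),
        )
        constraints = LinearConstraint(A, _inf(m["clb"]), _inf(m["cub"]))
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=bounds, options=options)
    if res.status == 0:
        status = "optimal"
    elif res.status == 2:
        status = "infeasible"
    else:
        status = "limit"
    return {
        "status": status,
        "objective": float(res.fun) if res.fun is not None else float("nan"),
        "x": [float(v) for v in res.x] if res.x is not None else [],
    }


def main(fin, fout):
    with open(fin) as fh:
        payload = json.load(fh)
    options = {"mip_rel_gap": float(payload.get("mip_gap", 0) or 0)}
    tl = float(payload.get("time_limit", -1) or -1)
    if tl > 0:
        options["time_limit"] = tl
    sols = [solve_one(m, options) for m in payload["models"]]
    with open(fout, "w") as fh:
        json.dump({"solutions": sols}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
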
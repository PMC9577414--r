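"""Exact transportation-LP oracle: solves each instance with scipy/HiGHS.

Input JSON: list of {"a": [...], "b": [...], "c": [[...], ...]} instances.
Output JSON: list of optimal objective values.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(inst):
    a = np.asarray(inst["a"], dtype=float)
    b = np.asarray(inst["b"], dtype=float)
    c = np.asarray(inst["c"], dtype=float)
    m, n = c.shape
    nv = m * n
    A_ub = np.zeros((m + n, nv))
    for i in range(m):
        A_ub[i, i * n:(i + 1) * n] = 1.0
    for j in range(n):
        A_ub[m + j, j::n] = 1.0
    b_ub = np.concatenate([a, b])
    A_eq = np.ones((1, nv))
    b_eq = [min(a.sum(), b.sum())]
    res = linprog(c.ravel(), A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                  bounds=(0, None), method="highs")
    assert res.status == 0, res.message
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    costs = [solve(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(costs, fh)


if __name__ == "__main__":
    main()
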
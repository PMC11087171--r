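{
  "name": "technique comparison scorecard",
  "side": "COMPARISON",
  "functions": [
    {
      "structure": "BreastCTV",
      "metric": "V47.5Gy[%]",
      "breakpoints": {
        "value": [90, 99, 100],
        "points": [0, 16, 20]
      },
      "benchmark_points": 16
    },
    {
      "structure": "BreastCTV",
      "metric": "V50Gy[%]",
      "breakpoints": {
        "value": [60, 98.3, 100],
        "points": [0, 16, 20]
      },
      "benchmark_points": 16
    },
    {
      "structure": "SclavCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 99.9, 100],
        "points": [0, 14, 18]
      },
      "benchmark_points": 14
    },
    {
      "structure": "AxillaCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 100],
        "points": [0, 15]
      },
      "benchmark_points": 12
    },
    {
      "structure": "IMNCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [75, 99.6, 100],
        "points": [0, 16, 20]
      },
      "benchmark_points": 16
    },
    {
      "structure": "Heart",
      "metric": "Mean[Gy]",
      "breakpoints": {
        "value": [5, 2, 0],
        "points": [0, 12, 15]
      },
      "benchmark_points": 12
    },
    {
      "structure": "Heart",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [53, 20, 0],
        "points": [0, 8, 10]
      },
      "benchmark_points": 8
    },
    {
      "structure": "IpsiLung",
      "metric": "V20Gy[%]",
      "breakpoints": {
        "value": [35, 19.6, 0],
        "points": [0, 12, 15]
      },
      "benchmark_points": 12
    },
    {
      "structure": "IpsiLung",
      "metric": "V5Gy[%]",
      "breakpoints": {
        "value": [55, 50, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "ContraLung",
      "metric": "V5Gy[%]",
      "breakpoints": {
        "value": [15, 0.1, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "Esophagus",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [50, 17, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "ContraBreast",
      "metric": "V5Gy[%]",
      "breakpoints": {
        "value": [10, 1.7, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    }
  ]
}
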
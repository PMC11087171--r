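{
  "name": "left-sided IMRT scorecard",
  "side": "LEFT",
  "functions": [
    {
      "structure": "BreastCTV",
      "metric": "V50Gy[%]",
      "breakpoints": {
        "value": [90, 97.9, 100],
        "points": [0, 14, 18]
      },
      "benchmark_points": 14
    },
    {
      "structure": "BreastCTV",
      "metric": "V52.5Gy[%]",
      "breakpoints": {
        "value": [20, 5, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "BreastPTV",
      "metric": "V50Gy[%]",
      "breakpoints": {
        "value": [90, 95.7, 100],
        "points": [0, 10, 13]
      },
      "benchmark_points": 10
    },
    {
      "structure": "BreastPTV",
      "metric": "V52.5Gy[%]",
      "breakpoints": {
        "value": [20, 5, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "SclavCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 100],
        "points": [0, 13]
      },
      "benchmark_points": 10.4
    },
    {
      "structure": "SclavCTV",
      "metric": "V47.25Gy[%]",
      "breakpoints": {
        "value": [90, 99.8, 100],
        "points": [0, 3, 4]
      },
      "benchmark_points": 3
    },
    {
      "structure": "SclavPTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 95.5, 100],
        "points": [0, 7, 9]
      },
      "benchmark_points": 7
    },
    {
      "structure": "SclavPTV",
      "metric": "V47.25Gy[%]",
      "breakpoints": {
        "value": [80, 85.6, 100],
        "points": [0, 3, 4]
      },
      "benchmark_points": 3
    },
    {
      "structure": "AxillaCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 100],
        "points": [0, 13]
      },
      "benchmark_points": 10.4
    },
    {
      "structure": "AxillaCTV",
      "metric": "V47.25Gy[%]",
      "breakpoints": {
        "value": [90, 99.6, 100],
        "points": [0, 3, 4]
      },
      "benchmark_points": 3
    },
    {
      "structure": "AxillaPTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 97.1, 100],
        "points": [0, 7, 9]
      },
      "benchmark_points": 7
    },
    {
      "structure": "AxillaPTV",
      "metric": "V47.25Gy[%]",
      "breakpoints": {
        "value": [85, 92.5, 100],
        "points": [0, 3, 4]
      },
      "benchmark_points": 3
    },
    {
      "structure": "IMNCTV",
      "metric": "V45Gy[%]",
      "breakpoints": {
        "value": [90, 99.2, 100],
        "points": [0, 10, 13]
      },
      "benchmark_points": 10
    },
    {
      "structure": "IMNCTV",
      "metric": "V47.25Gy[%]",
      "breakpoints": {
        "value": [80, 96.5, 100],
        "points": [0, 3, 4]
      },
      "benchmark_points": 3
    },
    {
      "structure": "Heart",
      "metric": "Mean[Gy]",
      "breakpoints": {
        "value": [5, 3, 0],
        "points": [0, 14, 18]
      },
      "benchmark_points": 14
    },
    {
      "structure": "Heart",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [53, 23.6, 0],
        "points": [0, 8, 10]
      },
      "benchmark_points": 8
    },
    {
      "structure": "IpsiLung",
      "metric": "V20Gy[%]",
      "breakpoints": {
        "value": [35, 19.3, 0],
        "points": [0, 11, 14]
      },
      "benchmark_points": 11
    },
    {
      "structure": "IpsiLung",
      "metric": "V5Gy[%]",
      "breakpoints": {
        "value": [55, 51, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "ContraLung",
      "metric": "V5Gy[%]",
      "breakpoints": {
        "value": [15, 0.2, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "Esophagus",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [50, 18.6, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "ContraBreast",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [4.96, 3.7, 0],
        "points": [0, 4, 5]
      },
      "benchmark_points": 4
    },
    {
      "structure": "Ring",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [55, 52.5, 45],
        "points": [0, 9.6, 12]
      },
      "benchmark_points": 9.6
    },
    {
      "structure": "Body",
      "metric": "D0.03cc[Gy]",
      "breakpoints": {
        "value": [55, 52.5, 45],
        "points": [0, 6.4, 8]
      },
      "benchmark_points": 6.4
    }
  ]
}
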
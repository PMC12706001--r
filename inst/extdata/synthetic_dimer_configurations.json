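[{"doublet_id":"synthetic_doublet_1","polarity":1,"outward_normal":[0,0,1],"axis":[[0,0,0],[900,0,0]],"heads":[{"head_id":1,"x":60,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":2,"x":66,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":3,"x":157.5,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":4,"x":165.5,"y":0.5,"z":12,"tubule":"A","dimer_id":2},{"head_id":5,"x":255,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":6,"x":247,"y":0.5,"z":12,"tubule":"A","dimer_id":3},{"head_id":7,"x":352.5,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":8,"x":360.5,"y":0.5,"z":12,"tubule":"A","dimer_id":4},{"head_id":9,"x":450,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":10,"x":458,"y":0.5,"z":12,"tubule":"A","dimer_id":5},{"head_id":11,"x":547.5,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":12,"x":539.5,"y":0.5,"z":12,"tubule":"A","dimer_id":6},{"head_id":13,"x":645,"y":4,"z":12,"tubule":"A","dimer_id":7},{"head_id":14,"x":637,"y":0.5,"z":12,"tubule":"A","dimer_id":7},{"head_id":15,"x":742.5,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":16,"x":742.5,"y":0.5,"z":12,"tubule":"A","dimer_id":8},{"head_id":17,"x":840,"y":4,"z":12,"tubule":"A","dimer_id":9},{"head_id":18,"x":848,"y":0.5,"z":12,"tubule":"A","dimer_id":9}],"true_classes":["other","1","3","1","1","3","3","2","1"]},{"doublet_id":"synthetic_doublet_2","polarity":1,"outward_normal":[0,0,1],"axis":[[0,0,0],[900,0,0]],"heads":[{"head_id":1,"x":60,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":2,"x":66,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":3,"x":157.5,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":4,"x":149.5,"y":0.5,"z":12,"tubule":"A","dimer_id":2},{"head_id":5,"x":255,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":6,"x":247,"y":0.5,"z":12,"tubule":"A","dimer_id":3},{"head_id":7,"x":352.5,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":8,"x":358.5,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":9,"x":450,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":10,"x":450,"y":0.5,"z":12,"tubule":"A","dimer_id":5},{"head_id":11,"x":547.5,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":12,"x":547.5,"y":0.5,"z":12,"tubule":"A","dimer_id":6},{"head_id":13,"x":645,"y":4,"z":12,"tubule":"A","dimer_id":7},{"head_id":14,"x":637,"y":0.5,"z":12,"tubule":"A","dimer_id":7},{"head_id":15,"x":742.5,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":16,"x":750.5,"y":0.5,"z":12,"tubule":"A","dimer_id":8},{"head_id":17,"x":840,"y":4,"z":12,"tubule":"A","dimer_id":9},{"head_id":18,"x":832,"y":0.5,"z":12,"tubule":"A","dimer_id":9}],"true_classes":["other","3","3","other","2","2","3","1","3"]},{"doublet_id":"synthetic_doublet_3","polarity":1,"outward_normal":[0,0,1],"axis":[[0,0,0],[900,0,0]],"heads":[{"head_id":1,"x":60,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":2,"x":52,"y":0.5,"z":12,"tubule":"A","dimer_id":1},{"head_id":3,"x":157.5,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":4,"x":163.5,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":5,"x":255,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":6,"x":261,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":7,"x":352.5,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":8,"x":352.5,"y":0.5,"z":12,"tubule":"A","dimer_id":4},{"head_id":9,"x":450,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":10,"x":442,"y":0.5,"z":12,"tubule":"A","dimer_id":5},{"head_id":11,"x":547.5,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":12,"x":553.5,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":13,"x":645,"y":4,"z":12,"tubule":"A","dimer_id":7},{"head_id":14,"x":653,"y":0.5,"z":12,"tubule":"A","dimer_id":7},{"head_id":15,"x":742.5,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":16,"x":748.5,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":17,"x":840,"y":4,"z":12,"tubule":"A","dimer_id":9},{"head_id":18,"x":832,"y":0.5,"z":12,"tubule":"A","dimer_id":9}],"true_classes":["3","other","other","2","3","other","1","other","3"]},{"doublet_id":"synthetic_doublet_4","polarity":1,"outward_normal":[0,0,1],"axis":[[0,0,0],[900,0,0]],"heads":[{"head_id":1,"x":60,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":2,"x":52,"y":0.5,"z":12,"tubule":"A","dimer_id":1},{"head_id":3,"x":171.428571428571,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":4,"x":171.428571428571,"y":0.5,"z":12,"tubule":"A","dimer_id":2},{"head_id":5,"x":282.857142857143,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":6,"x":274.857142857143,"y":0.5,"z":12,"tubule":"A","dimer_id":3},{"head_id":7,"x":394.285714285714,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":8,"x":394.285714285714,"y":0.5,"z":12,"tubule":"A","dimer_id":4},{"head_id":9,"x":505.714285714286,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":10,"x":505.714285714286,"y":0.5,"z":12,"tubule":"A","dimer_id":5},{"head_id":11,"x":617.142857142857,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":12,"x":623.142857142857,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":13,"x":728.571428571429,"y":4,"z":12,"tubule":"A","dimer_id":7},{"head_id":14,"x":728.571428571429,"y":0.5,"z":12,"tubule":"A","dimer_id":7},{"head_id":15,"x":840,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":16,"x":840,"y":0.5,"z":12,"tubule":"A","dimer_id":8}],"true_classes":["3","2","3","2","2","other","2","2"]},{"doublet_id":"synthetic_doublet_5","polarity":1,"outward_normal":[0,0,1],"axis":[[0,0,0],[900,0,0]],"heads":[{"head_id":1,"x":60,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":2,"x":66,"y":4,"z":12,"tubule":"A","dimer_id":1},{"head_id":3,"x":171.428571428571,"y":4,"z":12,"tubule":"A","dimer_id":2},{"head_id":4,"x":163.428571428571,"y":0.5,"z":12,"tubule":"A","dimer_id":2},{"head_id":5,"x":282.857142857143,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":6,"x":288.857142857143,"y":4,"z":12,"tubule":"A","dimer_id":3},{"head_id":7,"x":394.285714285714,"y":4,"z":12,"tubule":"A","dimer_id":4},{"head_id":8,"x":394.285714285714,"y":0.5,"z":12,"tubule":"A","dimer_id":4},{"head_id":9,"x":505.714285714286,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":10,"x":511.714285714286,"y":4,"z":12,"tubule":"A","dimer_id":5},{"head_id":11,"x":617.142857142857,"y":4,"z":12,"tubule":"A","dimer_id":6},{"head_id":12,"x":625.142857142857,"y":0.5,"z":12,"tubule":"A","dimer_id":6},{"head_id":13,"x":728.571428571429,"y":4,"z":12,"tubule":"A","dimer_id":7},{"head_id":14,"x":728.571428571429,"y":0.5,"z":12,"tubule":"A","dimer_id":7},{"head_id":15,"x":840,"y":4,"z":12,"tubule":"A","dimer_id":8},{"head_id":16,"x":846,"y":4,"z":12,"tubule":"A","dimer_id":8}],"true_classes":["other","3","other","2","other","1","2","other"]}]
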
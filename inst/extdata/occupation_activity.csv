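occupation,activity
"Executive, administrator, manager",low
Professional specialty,low
Engineer,low
Teacher,low
Technician,low
Secretary,low
Administrative support or clerical,low
Sales representative,low
"Writer, artist, entertainer",low
Health diagnosing professional,low
Construction worker,high
Machine operator,high
Agricultural worker,high
Waiter,high
Cook,high
Cleaner or building service,high
Protective service,high
Laborer or helper,high
Truck driver,high
Mechanic or repairer,high
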
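configuration	fold	sens	spec	accuracy
vgg	1	26.304	93.899	69.597
vgg	2	77.417	54.273	68.584
vgg	average	66.271	71.946	68.912
inception	1	78.370	57.352	64.908
inception	2	89.967	30.501	67.272
inception	average	87.438	42.476	66.505
densenet	1	35.978	85.174	67.487
densenet	2	14.974	94.892	45.473
densenet	average	19.554	90.558	52.609
max	1	52.283	82.977	71.942
max	2	59.533	63.703	61.124
max	average	57.952	72.299	64.630
average	1	42.500	88.896	72.215
average	2	75.690	61.002	70.084
average	average	68.452	73.442	70.775
voting	1	41.413	88.286	71.434
voting	2	75.993	59.921	69.859
voting	average	68.452	72.571	70.369
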
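{"entry":"input","exit":"output","input_size":32,"num_classes":5,"layers":[{"id":"input","kind":"input","in_channels":3,"out_channels":3,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"","section":"stem","convertible":true,"path":0},{"id":"conv1","kind":"conv","in_channels":3,"out_channels":16,"kernel":3,"stride":1,"padding":1,"groups":1,"bias":false,"predecessors":"input","section":"features","convertible":true,"path":0},{"id":"bn1","kind":"batchnorm","in_channels":16,"out_channels":16,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"conv1","section":"features","convertible":true,"path":0},{"id":"relu1","kind":"relu","in_channels":16,"out_channels":16,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"bn1","section":"features","convertible":true,"path":0},{"id":"conv2","kind":"conv","in_channels":16,"out_channels":32,"kernel":3,"stride":1,"padding":1,"groups":1,"bias":false,"predecessors":"relu1","section":"features","convertible":true,"path":0},{"id":"bn2","kind":"batchnorm","in_channels":32,"out_channels":32,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"conv2","section":"features","convertible":true,"path":0},{"id":"relu2","kind":"relu","in_channels":32,"out_channels":32,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"bn2","section":"features","convertible":true,"path":0},{"id":"conv3","kind":"conv","in_channels":32,"out_channels":64,"kernel":3,"stride":1,"padding":1,"groups":1,"bias":false,"predecessors":"relu2","section":"features","convertible":true,"path":0},{"id":"bn3","kind":"batchnorm","in_channels":64,"out_channels":64,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"conv3","section":"features","convertible":true,"path":0},{"id":"relu3","kind":"relu","in_channels":64,"out_channels":64,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"bn3","section":"features","convertible":true,"path":0},{"id":"gap","kind":"globalavgpool","in_channels":64,"out_channels":64,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"relu3","section":"features","convertible":true,"path":0},{"id":"flat","kind":"flatten","in_channels":64,"out_channels":64,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"gap","section":"features","convertible":true,"path":0},{"id":"classifier","kind":"dense","in_channels":64,"out_channels":5,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":true,"predecessors":"flat","section":"head","convertible":true,"path":0},{"id":"output","kind":"output","in_channels":5,"out_channels":5,"kernel":1,"stride":1,"padding":0,"groups":1,"bias":false,"predecessors":"classifier","section":"head","convertible":true,"path":0}]}
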
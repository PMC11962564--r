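# Markups fiducial file version = 4.11
# CoordinateSystem = RAS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
vtkMRMLMarkupsFiducialNode_0,-12.1,45.3,1401.2,0,0,0,1,1,1,0,AA,,
vtkMRMLMarkupsFiducialNode_1,-18.6,166.0,1462.9,0,0,0,1,1,1,0,IA,,
vtkMRMLMarkupsFiducialNode_2,-10.9,44.8,1501.5,0,0,0,1,1,1,0,TS,,
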
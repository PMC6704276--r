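<?xml version="1.0" encoding="UTF-8"?>
<ImageData>
  <GlobalCoordinates>1</GlobalCoordinates>
  <X_CalibrationPoint_1>0</X_CalibrationPoint_1>
  <Y_CalibrationPoint_1>0</Y_CalibrationPoint_1>
  <X_CalibrationPoint_2>800</X_CalibrationPoint_2>
  <Y_CalibrationPoint_2>20</Y_CalibrationPoint_2>
  <X_CalibrationPoint_3>50</X_CalibrationPoint_3>
  <Y_CalibrationPoint_3>750</Y_CalibrationPoint_3>
  <ShapeCount>3</ShapeCount>
  <Shape_1>
    <PointCount>5</PointCount>
    <CapID>1</CapID>
    <X_1>50</X_1>
    <Y_1>50</Y_1>
    <X_2>52</X_2>
    <Y_2>50</Y_2>
    <X_3>52</X_3>
    <Y_3>52</Y_3>
    <X_4>50</X_4>
    <Y_4>52</Y_4>
    <X_5>50</X_5>
    <Y_5>50</Y_5>
  </Shape_1>
  <Shape_2>
    <PointCount>2</PointCount>
    <CapID>1</CapID>
    <X_1>300</X_1>
    <Y_1>200</Y_1>
    <X_2>300</X_2>
    <Y_2>200</Y_2>
  </Shape_2>
  <Shape_3>
    <PointCount>4</PointCount>
    <CapID>2</CapID>
    <X_1>200</X_1>
    <Y_1>101</Y_1>
    <X_2>206</X_2>
    <Y_2>101</Y_2>
    <X_3>206</X_3>
    <Y_3>108</Y_3>
    <X_4>200</X_4>
    <Y_4>101</Y_4>
  </Shape_3>
</ImageData>
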